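#' Fit a two-parameter logistic item response model
#'
#' Marginal maximum likelihood for binary item responses under
#' \deqn{P(y_{ij}=1 \mid \theta_j) = \mathrm{logit}^{-1}\{a_i(\theta_j - b_i)\},
#' \qquad \theta_j \sim N(0, 1),}
#' where \eqn{a_i > 0} is item discrimination (how sharply item availability
#' separates facilities of different latent readiness) and \eqn{b_i} is item
#' difficulty (the latent readiness level at which availability crosses
#' 50%). The latent trait is integrated out by Gauss--Hermite quadrature and
#' the marginal likelihood maximised by EM: the E-step computes each
#' facility's posterior weight at every quadrature node, the M-step refits
#' one weighted logistic regression per item on the node locations.
#'
#' Cells masked as not applicable contribute nothing to the likelihood.
#'
#' @param matrix a `response_matrix` (additive coding preserves the
#'   applicability mask) or a plain 0/1 matrix (facilities x items; `NA`
#'   cells are treated as not applicable).
#' @param n_quadrature number of Gauss--Hermite nodes (default 21).
#' @param max_iter EM iteration cap (default 500).
#' @param tol convergence threshold on the largest absolute parameter change
#'   (default 1e-4).
#' @param a_bounds,b_bounds box constraints keeping estimates identified on
#'   small or quasi-degenerate samples; defaults (0.05, 10) and (-6, 6).
#' @return object of class `twopl`: `coefficients` (data frame `item_id`,
#'   `a`, `b`), `logLik`, `logLik_trace`, `converged`, `n_iter`,
#'   `n_quadrature`, `nodes`, `node_weights`, `n_facilities`.
#' @export
#' @examples
#' set.seed(11)
#' theta <- rnorm(400)
#' y <- sapply(c(-1, 0, 1), function(b) rbinom(400, 1, plogis(1.3 * (theta - b))))
#' colnames(y) <- paste0("it", 1:3)
#' fit <- fit_2pl(y)
#' coef(fit)
fit_2pl <- function(matrix, n_quadrature = 21, max_iter = 500, tol = 1e-4,
                    a_bounds = c(0.05, 10), b_bounds = c(-6, 6)) {
  if (inherits(matrix, "response_matrix")) {
    y <- matrix$values
    mask <- matrix$applicable
  } else {
    y <- as.matrix(matrix)
    mask <- !is.na(y)
    y[!mask] <- 0L
  }
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  if (ncol(y) < 2) {
    stop_cbready("2PL fit needs at least 2 items", "cbready_insufficient_data")
  }
  avail <- colSums(y * mask) / colSums(mask)
  degen <- colnames(y)[avail %in% c(0, 1)]
  if (length(degen) > 0) {
    stop_cbready(sprintf("all-constant item(s), 2PL parameters unidentified: %s",
                         paste(degen, collapse = ", ")),
                 "cbready_degenerate_item")
  }
  gh <- pracma::gaussHermite(n_quadrature)
  nodes <- sqrt(2) * gh$x                # N(0,1) abscissae
  wq <- gh$w / sqrt(pi)                  # prior weights, sum to 1
  n <- nrow(y)
  p_items <- ncol(y)

  # start values: difficulty from the marginal availability, moderate slope
  a <- rep(1, p_items)
  b <- -stats::qlogis(avail)
  b <- pmin(pmax(b, b_bounds[1]), b_bounds[2])

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  X <- cbind(1, nodes)
  for (iter in seq_len(max_iter)) {
    # E-step: log-likelihood of each facility at each node
    eta <- outer(nodes, b, "-") * rep(a, each = n_quadrature)   # q x items
    logp <- stats::plogis(eta, log.p = TRUE)
    log1mp <- stats::plogis(-eta, log.p = TRUE)
    # facility x node log-likelihood: sum over applicable items
    llm <- tcrossprod(y * mask, logp) + tcrossprod((1 - y) * mask, log1mp)
    llm <- sweep(llm, 2, log(wq), "+")
    m <- apply(llm, 1, max)
    lik <- exp(llm - m)
    denom <- rowSums(lik)
    post <- lik / denom                                  # n x q
    ll <- sum(m + log(denom))
    ll_trace <- c(ll_trace, ll)

    # expected per-node counts, per item (mask-aware)
    nq_i <- crossprod(post, mask)                        # q x items trials
    rq_i <- crossprod(post, y * mask)                    # q x items successes
    a_new <- a
    b_new <- b
    for (i in seq_len(p_items)) {
      wts <- nq_i[, i]
      pr <- ifelse(wts > 0, rq_i[, i] / wts, 0)
      fit <- suppressWarnings(
        stats::glm.fit(X, pr, weights = wts, family = stats::binomial(),
                       start = c(-a[i] * b[i], a[i]))
      )
      slope <- fit$coefficients[2]
      inter <- fit$coefficients[1]
      if (!is.finite(slope) || slope <= 0) slope <- a_bounds[1]
      slope <- min(max(slope, a_bounds[1]), a_bounds[2])
      bb <- -inter / slope
      if (!is.finite(bb)) bb <- 0
      a_new[i] <- slope
      b_new[i] <- min(max(bb, b_bounds[1]), b_bounds[2])
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new
    b <- b_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    coefficients = data.frame(item_id = colnames(y), a = unname(a),
                              b = unname(b), stringsAsFactors = FALSE),
    logLik = ll_trace[length(ll_trace)],
    logLik_trace = ll_trace,
    converged = converged,
    n_iter = iter,
    n_quadrature = n_quadrature,
    nodes = nodes,
    node_weights = wq,
    n_facilities = n
  ), class = "twopl")
}

#' @export
print.twopl <- function(x, ...) {
  cat(sprintf("Two-parameter logistic IRT fit: %d items, %d facilities\n",
              nrow(x$coefficients), x$n_facilities))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$logLik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.twopl <- function(object, ...) {
  stats::setNames(
    c(object$coefficients$a, object$coefficients$b),
    c(paste0("a.", object$coefficients$item_id),
      paste0("b.", object$coefficients$item_id))
  )
}

#' @export
logLik.twopl <- function(object, ...) {
  structure(object$logLik, df = 2 * nrow(object$coefficients),
            nobs = object$n_facilities, class = "logLik")
}

#' @export
summary.twopl <- function(object, ...) {
  co <- object$coefficients
  cat(sprintf("2PL fit on %d items (%d facilities), logLik %.2f\n",
              nrow(co), object$n_facilities, object$logLik))
  cat(sprintf("  discrimination a: median %.2f, range [%.2f, %.2f]\n",
              stats::median(co$a), min(co$a), max(co$a)))
  cat(sprintf("  difficulty b: median %.2f, range [%.2f, %.2f]\n",
              stats::median(co$b), min(co$b), max(co$b)))
  invisible(object)
}

#' Item characteristic curves of a fitted 2PL model
#'
#' @param x a `twopl` fit.
#' @param theta latent-trait grid.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.twopl <- function(x, theta = seq(-4, 4, length.out = 101), ...) {
  co <- x$coefficients
  p <- sapply(seq_len(nrow(co)),
              function(i) stats::plogis(co$a[i] * (theta - co$b[i])))
  graphics::matplot(theta, p, type = "l", lty = 1,
                    xlab = expression(theta), ylab = "P(item available)",
                    main = "Item characteristic curves", ...)
  invisible(x)
}

#' Simulate binary responses from a fitted 2PL model
#'
#' @param object a `twopl` fit.
#' @param nsim number of facilities to simulate.
#' @param seed optional RNG seed.
#' @param theta optional latent-trait vector (length `nsim`); drawn from
#'   N(0, 1) when absent.
#' @param ... unused.
#' @return 0/1 matrix `nsim` x items.
#' @export
simulate.twopl <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(nsim)
  co <- object$coefficients
  y <- sapply(seq_len(nrow(co)), function(i) {
    stats::rbinom(length(theta), 1, stats::plogis(co$a[i] * (theta - co$b[i])))
  })
  colnames(y) <- co$item_id
  y
}
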