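# Two-component univariate Gaussian mixture fitted by EM with BIC choice
# between equal- and unequal-variance models; classification of activity
# scores into mutant-like (lower-mean component) and wildtype-like.

.em_gmm2 <- function(x, equal_var, mu, sd2, w, max_iter, tol) {
  n <- length(x)
  var_floor <- max(stats::var(x) * 1e-8, .Machine$double.eps)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sqrt(sd2[1L]))
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sqrt(sd2[2L]))
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r1 <- d1 / tot
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    if (equal_var) {
      v <- (sum(r1 * (x - mu[1L])^2) + sum((1 - r1) * (x - mu[2L])^2)) / n
      sd2 <- c(v, v)
    } else {
      sd2 <- c(sum(r1 * (x - mu[1L])^2) / n1,
               sum((1 - r1) * (x - mu[2L])^2) / n2)
    }
    sd2 <- pmax(sd2, var_floor)
    w <- c(n1 / n, n2 / n)
  }
  list(mu = mu, sd = sqrt(sd2), w = w, loglik = ll_old,
       converged = converged)
}

.mixture_inits <- function(x, n_init) {
  s <- stats::sd(x)
  inits <- list(list(mu = c(mean(x[x <= stats::median(x)]),
                            mean(x[x > stats::median(x)])),
                     sd2 = rep(stats::var(x) / 2, 2L),
                     w = c(0.5, 0.5)))
  for (i in seq_len(n_init)) {
    mu <- sort(sample(x, 2L))
    if (diff(mu) < 1e-12) mu <- mu + c(-0.1, 0.1) * max(s, 1e-6)
    inits[[length(inits) + 1L]] <-
      list(mu = mu, sd2 = rep(max(stats::var(x) / 4, 1e-12), 2L),
           w = c(0.5, 0.5))
  }
  inits
}

#' Fit a two-component Gaussian mixture to activity scores
#'
#' Univariate two-component Gaussian mixture fitted by EM under both an
#' equal-variance and an unequal-variance model; the model with the lower
#' BIC is returned. Initialization uses a median split plus `n_init` random
#' restarts (seeded, so the fit is deterministic given `seed`), keeping the
#' best log-likelihood per model. Components are ordered so component 1 has
#' the lower mean and is interpreted as mutant-like. The classification
#' threshold is the score between the two means where the posterior
#' probability of the mutant-like component crosses 0.5.
#'
#' @param scores A score table (`data.frame` with a `score` column, see
#'   [weighted_score()]) or a numeric vector. Needs >= 10 finite,
#'   non-identical values.
#' @param n_init Number of random restarts beyond the median-split start.
#' @param seed Optional integer seed controlling the random restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `mixture_fit`: list with `means`, `sds`,
#'   `weights` (component 1 = lower mean), `variance_mode`
#'   (`"equal"`/`"unequal"`), `loglik`, `bic` (lower is better), `threshold`,
#'   `converged`, `n`.
#' @export
fit_score_mixture <- function(scores, n_init = 10L, seed = NULL,
                              max_iter = 500L, tol = 1e-8) {
  x <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("need >= 10 finite scores", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate input: all scores identical", call. = FALSE)
  }
  run <- function() {
    inits <- .mixture_inits(x, n_init)
    fits <- list()
    for (mode in c("equal", "unequal")) {
      best <- NULL
      for (init in inits) {
        f <- .em_gmm2(x, equal_var = (mode == "equal"), mu = init$mu,
                      sd2 = init$sd2, w = init$w, max_iter = max_iter,
                      tol = tol)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      k <- if (mode == "equal") 4L else 5L
      best$bic <- -2 * best$loglik + k * log(length(x))
      best$variance_mode <- mode
      fits[[mode]] <- best
    }
    if (fits$equal$bic <= fits$unequal$bic) fits$equal else fits$unequal
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ord <- order(fit$mu)
  fit$mu <- fit$mu[ord]; fit$sd <- fit$sd[ord]; fit$w <- fit$w[ord]
  out <- structure(list(
    means = fit$mu, sds = fit$sd, weights = fit$w,
    variance_mode = fit$variance_mode, loglik = fit$loglik, bic = fit$bic,
    converged = fit$converged, n = length(x)), class = "mixture_fit")
  out$threshold <- .mixture_threshold(out)
  out
}

# posterior probability of the mutant-like (lower-mean) component
.posterior_mutant <- function(fit, x) {
  d1 <- fit$weights[1L] * stats::dnorm(x, fit$means[1L], fit$sds[1L])
  d2 <- fit$weights[2L] * stats::dnorm(x, fit$means[2L], fit$sds[2L])
  tot <- d1 + d2
  p <- ifelse(tot > 0, d1 / tot, as.numeric(x < mean(fit$means)))
  p
}

.mixture_threshold <- function(fit) {
  m1 <- fit$means[1L]; m2 <- fit$means[2L]
  if (abs(m2 - m1) < 1e-12) return(m1)
  f <- function(x) .posterior_mutant(fit, x) - 0.5
  if (sign(f(m1)) != sign(f(m2)) && abs(f(m1)) > 0 && abs(f(m2)) > 0) {
    return(stats::uniroot(f, lower = m1, upper = m2, tol = 1e-10)$root)
  }
  # extreme weights can keep the posterior on one side between the means;
  # fall back to the grid point closest to posterior 0.5
  grid <- seq(m1, m2, length.out = 2048L)
  grid[which.min(abs(f(grid)))]
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("2-component Gaussian mixture (%s variance), n = %d\n",
              x$variance_mode, x$n))
  cat(sprintf("  means %.4g / %.4g, sds %.4g / %.4g, weights %.3f / %.3f\n",
              x$means[1L], x$means[2L], x$sds[1L], x$sds[2L],
              x$weights[1L], x$weights[2L]))
  cat(sprintf("  logLik %.3f, BIC %.3f, threshold %.4g, converged: %s\n",
              x$loglik, x$bic, x$threshold, x$converged))
  invisible(x)
}

#' Classify scores with a fitted mixture
#'
#' Computes each sample's posterior probability of the mutant-like
#' (lower-mean) component under a [fit_score_mixture()] fit and assigns
#' `mutant-like` when the posterior exceeds 0.5 (ties go to
#' `wildtype-like`). Non-finite scores are rejected with their sample ids.
#'
#' @param scores Score table with `sample_id` and `score` columns.
#' @param fit A `mixture_fit`.
#' @param truth Optional character vector of true statuses (`"mutant"` /
#'   `"wildtype"`) aligned to `scores` rows, used for the agreement summary.
#' @return A list with `classes` (a `data.frame` of `sample_id`, `score`,
#'   `posterior_mutant_like`, `class`) and `summary` (`n`,
#'   `fraction_mutant_like`, and when `truth` is given `agreement` plus the
#'   fraction of true mutants classified mutant-like).
#' @export
classify_scores <- function(scores, fit, truth = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  bad <- which(!is.finite(scores$score))
  if (length(bad)) {
    stop("non-finite score for sample(s): ",
         paste(utils::head(scores$sample_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  post <- .posterior_mutant(fit, scores$score)
  cls <- ifelse(post > 0.5, "mutant-like", "wildtype-like")
  classes <- data.frame(sample_id = scores$sample_id, score = scores$score,
                        posterior_mutant_like = post, class = cls,
                        stringsAsFactors = FALSE)
  summary <- list(n = nrow(classes),
                  fraction_mutant_like = mean(cls == "mutant-like"))
  if (!is.null(truth)) {
    stopifnot(length(truth) == nrow(scores))
    pred_mut <- cls == "mutant-like"
    true_mut <- truth == "mutant"
    summary$agreement <- mean(pred_mut == true_mut)
    summary$fraction_true_mutant_classified_mutant_like <-
      if (any(true_mut)) mean(pred_mut[true_mut]) else NA_real_
  }
  list(classes = classes, summary = summary)
}

#' Classify scores against a frozen threshold
#'
#' Applies an externally supplied threshold (e.g. from a mixture fitted on a
#' reference cohort): `mutant-like` iff `score < threshold`.
#'
#' @param scores Score table with `sample_id` and `score`.
#' @param threshold Finite numeric threshold.
#' @return A `data.frame` of `sample_id`, `score`, `class`.
#' @export
apply_external_threshold <- function(scores, threshold) {
  stopifnot(is.finite(threshold))
  data.frame(sample_id = scores$sample_id, score = scores$score,
             class = ifelse(scores$score < threshold, "mutant-like",
                            "wildtype-like"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a mixture fit as JSON
#' @param fit A `mixture_fit`.
#' @param path Output (input) JSON path.
#' @return `write_mixture_fit`: `path` invisibly; `read_mixture_fit`: the
#'   restored `mixture_fit`.
#' @export
write_mixture_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_fit
#' @export
read_mixture_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "mixture_fit")
}
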