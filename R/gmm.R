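#' Fit a two-channel Gaussian mixture model by seeded EM
#'
#' Fits a K-component mixture with full 2x2 covariances to the (normalized)
#' ADC/T2W feature cloud by expectation-maximization: k-means++-style seeded
#' initialization, a 1e-6 ridge on covariance diagonals against singular
#' components, at most 500 iterations, relative log-likelihood tolerance
#' 1e-6. The fit is a pure function of (data, K, seed). Hard labels are the
#' argmax responsibility per observation.
#'
#' Alongside the mixture parameters in normalized space, the fit records each
#' component's mean raw (un-normalized) ADC and T2W over its member voxels;
#' the stroke-component selection rule operates on those raw means only, so
#' it is invariant to how the feature space was scaled for fitting.
#'
#' @param features feature table (normalized channels) or an n x 2 matrix
#'   with columns (adc, t2w).
#' @param K number of mixture components, >= 1.
#' @param seed integer seed.
#' @param raw the corresponding un-normalized features (same row order);
#'   defaults to `features` itself, which is correct when fitting raw data.
#' @param max_iter,tol,reg EM controls: iteration cap, relative
#'   log-likelihood tolerance, covariance diagonal ridge.
#' @param fit_subsample if non-NULL and smaller than the number of rows, EM
#'   runs on a seeded subsample of this size and the full dataset is then
#'   labeled by one E-step under the fitted parameters. Component member
#'   statistics (counts, raw means) always refer to the full dataset.
#' @return object of class `gmm_fit`: `K`, `weights`, `means` (K x 2,
#'   normalized space), `covariances` (list of 2x2), `labels` (1..K per
#'   observation), `counts`, `mu_adc`/`mu_t2w` (raw member means),
#'   `loglik`, `n_iter`, `converged`, `seed`, `stroke_component` (NA until
#'   [select_stroke_component()] is applied).
#' @export
fit_gmm <- function(features, K, seed, raw = NULL,
                    max_iter = 500, tol = 1e-6, reg = 1e-6,
                    fit_subsample = NULL) {
  x <- feature_matrix(features)
  xr <- if (is.null(raw)) x else feature_matrix(raw)
  stopifnot(nrow(xr) == nrow(x), K >= 1)
  n <- nrow(x)
  if (n < K) stop("need at least K observations to fit K components")
  if (any(!is.finite(x))) stop("validation error: non-finite feature values")

  xfit <- x
  if (!is.null(fit_subsample) && fit_subsample < n) {
    idx <- with_seed(derive_seed(seed, "subsample"),
                     sample.int(n, fit_subsample))
    xfit <- x[idx, , drop = FALSE]
  }

  par <- with_seed(seed, em_gmm(xfit, K, max_iter = max_iter, tol = tol, reg = reg))
  finish_gmm_fit(par, x, xr, K, seed)
}

# label the full dataset under fitted parameters and assemble the fit object
finish_gmm_fit <- function(par, x, xr, K, seed) {
  lw <- log(pmax(par$weights, 1e-300))
  ld <- component_logdens(x, par$means, par$covariances)
  labels <- max.col(sweep(ld, 2, lw, "+"), ties.method = "first")
  counts <- tabulate(labels, nbins = K)
  mu_adc <- mu_t2w <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (counts[k] > 0) {
      mu_adc[k] <- mean(xr[labels == k, 1])
      mu_t2w[k] <- mean(xr[labels == k, 2])
    }
  }
  structure(list(K = K, weights = par$weights, means = par$means,
                 covariances = par$covariances, labels = labels,
                 counts = counts, mu_adc = mu_adc, mu_t2w = mu_t2w,
                 loglik = par$loglik, n_iter = par$n_iter %||% NA_integer_,
                 converged = par$converged %||% TRUE, seed = seed,
                 stroke_component = NA_integer_),
            class = "gmm_fit")
}

feature_matrix <- function(features) {
  if (is.matrix(features)) {
    stopifnot(ncol(features) == 2)
    colnames(features) <- c("adc", "t2w")
    return(features)
  }
  as.matrix(features[, c("adc", "t2w")])
}

# log N(x | mu_k, S_k) for all k, closed form for 2x2 covariances
component_logdens <- function(x, means, covs) {
  n <- nrow(x); K <- nrow(means)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    S <- covs[[k]]
    det <- S[1, 1] * S[2, 2] - S[1, 2]^2
    d1 <- x[, 1] - means[k, 1]; d2 <- x[, 2] - means[k, 2]
    q <- (S[2, 2] * d1 * d1 - 2 * S[1, 2] * d1 * d2 + S[1, 1] * d2 * d2) / det
    out[, k] <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
  }
  out
}

# k-means++ center seeding (uses the current RNG stream)
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (k in 2:K) {
      p <- d2 / sum(d2)
      centers[k, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
    }
  }
  centers
}

# EM iterations from given parameters (the shared workhorse)
em_run <- function(x, w, means, covs, max_iter, tol, reg) {
  n <- nrow(x); K <- length(w)
  ll_prev <- -Inf; converged <- FALSE; it <- 0L; ll <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(component_logdens(x, means, covs), 2, log(pmax(w, 1e-300)), "+")
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)
    nk <- colSums(r)
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next  # collapsed component: freeze its parameters
      means[k, ] <- colSums(r[, k] * x) / nk[k]
      d1 <- x[, 1] - means[k, 1]; d2 <- x[, 2] - means[k, 2]
      S <- matrix(c(sum(r[, k] * d1 * d1), sum(r[, k] * d1 * d2),
                    sum(r[, k] * d1 * d2), sum(r[, k] * d2 * d2)) / nk[k], 2, 2)
      covs[[k]] <- S + diag(reg, 2)
    }
    w <- nk / n
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(weights = w, means = means, covariances = covs, loglik = ll,
       n_iter = it, converged = converged)
}

# initial parameters from a hard partition
params_from_partition <- function(x, assign0, K, reg) {
  w <- tabulate(assign0, K) / nrow(x)
  means <- t(vapply(seq_len(K), function(k)
    colMeans(x[assign0 == k, , drop = FALSE]), numeric(2)))
  covs <- lapply(seq_len(K), function(k) {
    xs <- x[assign0 == k, , drop = FALSE]
    S <- if (nrow(xs) > 1) stats::cov(xs) * (nrow(xs) - 1) / nrow(xs) else diag(2)
    S + diag(reg, 2)
  })
  list(weights = w, means = means, covariances = covs)
}

em_gmm <- function(x, K, max_iter, tol, reg) {
  n <- nrow(x)
  if (K == 1) {
    mu <- colMeans(x)
    S <- stats::cov(x) * (n - 1) / n + diag(reg, 2)
    ll <- sum(component_logdens(x, matrix(mu, 1), list(S)))
    return(list(weights = 1, means = matrix(mu, 1, 2), covariances = list(S),
                loglik = ll, n_iter = 0L, converged = TRUE))
  }
  centers <- unique(kmeanspp_centers(x, K))
  km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = centers,
                                                iter.max = 25)),
                 error = function(e) NULL)
  assign0 <- if (!is.null(km) && length(unique(km$cluster)) == K) km$cluster
             else ((sample.int(n) - 1) %% K) + 1L
  p0 <- params_from_partition(x, assign0, K, reg)
  out <- em_run(x, p0$weights, p0$means, p0$covariances, max_iter, tol, reg)
  if (!out$converged) {
    warning("EM did not converge within ", max_iter, " iterations (K = ", K, ")")
  }
  out
}

# total mixture log-density per observation
mixture_logdens <- function(x, w, means, covs) {
  lp <- sweep(component_logdens(x, means, covs), 2, log(pmax(w, 1e-300)), "+")
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("gmm_fit: K =", x$K, "| loglik", format(x$loglik), "|",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  tab <- data.frame(component = seq_len(x$K), weight = round(x$weights, 4),
                    n = x$counts, mu_adc = round(x$mu_adc, 1),
                    mu_t2w = round(x$mu_t2w, 1))
  print(tab, row.names = FALSE)
  if (!is.na(x$stroke_component)) cat("stroke component:", x$stroke_component, "\n")
  invisible(x)
}

#' Assign mixture labels to new observations
#'
#' One E-step under the fitted parameters: each observation receives the
#' component with maximal posterior responsibility.
#'
#' @param object a [fit_gmm()] result.
#' @param newdata feature table or n x 2 matrix in the same (normalized)
#'   space the model was fitted in.
#' @param ... unused.
#' @return integer labels in 1..K.
#' @export
predict.gmm_fit <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  lp <- sweep(component_logdens(x, object$means, object$covariances), 2,
              log(pmax(object$weights, 1e-300)), "+")
  max.col(lp, ties.method = "first")
}

#' Select the stroke component of a fitted mixture
#'
#' The acute ischemic core is the cluster with reduced ADC and elevated T2W.
#' The default rule scores each component by the ratio of its mean raw T2W to
#' its mean raw ADC and selects the maximizer; ties break to the lowest
#' component index. Because the score uses un-normalized member means only,
#' the selection is invariant to any rescaling of the fitting space.
#'
#' @param fit a [fit_gmm()] result.
#' @param rule `"t2w_over_adc"` (default, argmax mu_T2W/mu_ADC),
#'   `"adc_over_t2w"` (argmin mu_ADC/mu_T2W — the same ordering, offered as a
#'   cross-check), or `"lexicographic"` (lowest mu_ADC, ties by highest
#'   mu_T2W).
#' @return the selected component index. Store it with
#'   `fit$stroke_component <- select_stroke_component(fit)`; the pipeline and
#'   [select_model_order()] do this automatically.
#' @export
select_stroke_component <- function(fit,
                                    rule = c("t2w_over_adc", "adc_over_t2w",
                                             "lexicographic")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "gmm_fit"))
  eligible <- fit$counts > 0
  if (any(!eligible)) {
    warning("excluding ", sum(!eligible), " empty component(s) from stroke selection")
  }
  if (!any(eligible)) stop("degenerate-component error: all components empty")
  if (any(fit$mu_adc[eligible] <= 0)) {
    stop("degenerate-component error: component with non-positive mean ADC")
  }
  idx <- which(eligible)
  score <- switch(rule,
    t2w_over_adc = fit$mu_t2w[idx] / fit$mu_adc[idx],
    adc_over_t2w = -(fit$mu_adc[idx] / fit$mu_t2w[idx]),
    lexicographic = -(fit$mu_adc[idx] + fit$mu_t2w[idx] * 0))
  if (rule == "lexicographic") {
    best <- idx[order(fit$mu_adc[idx], -fit$mu_t2w[idx], idx)[1]]
  } else {
    best <- idx[which(score == max(score))]
    best <- min(best)  # tie-break: lowest component index
  }
  best
}

#' Contralateral stroke fraction of a fitted mixture
#'
#' The contralateral hemisphere is a lesion-free negative control, so voxels
#' of the stroke cluster found there are spurious. The fraction of the stroke
#' cluster lying contralateral is the model-order selection statistic.
#'
#' @param fit a [fit_gmm()] with `stroke_component` set.
#' @param hemisphere integer vector (1 ipsilateral, 2 contralateral), one per
#'   observation of the fit.
#' @param denominator `"stroke_cluster"` (default: fraction of the stroke
#'   cluster that is contralateral) or `"contralateral"` (fraction of all
#'   contralateral voxels captured by the stroke cluster).
#' @return a fraction in \[0, 1\].
#' @export
contralateral_fraction <- function(fit, hemisphere,
                                   denominator = c("stroke_cluster",
                                                   "contralateral")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(fit, "gmm_fit"), length(hemisphere) == length(fit$labels))
  if (is.na(fit$stroke_component)) {
    stop("stroke_component not set; run select_stroke_component() first")
  }
  members <- fit$labels == fit$stroke_component
  if (!any(members)) stop("undefined-fraction error: stroke cluster is empty")
  num <- sum(members & hemisphere == 2)
  den <- if (denominator == "stroke_cluster") sum(members) else sum(hemisphere == 2)
  if (den == 0) stop("undefined-fraction error: empty denominator")
  num / den
}

#' Plateau rule on a contralateral-fraction sequence
#'
#' Chooses the smallest model order K whose fraction improves by less than
#' `eps` at the next scanned step: from there on, adding components no
#' longer reduces the contralateral stroke fraction meaningfully and only
#' subdivides the stroke cluster at increased model complexity. Stopping at
#' the first plateau is deliberate — at much larger K the stroke cluster
#' eventually fragments into tight subclusters whose fractions can drop
#' spuriously to zero, so a rule that hunted the global minimum would chase
#' exactly the degenerate solutions the selection is meant to avoid. If no
#' plateau occurs within the scanned range, the largest K is returned with
#' a warning.
#'
#' @param fractions contralateral stroke fractions, one per K.
#' @param K the model orders scanned, strictly increasing.
#' @param eps absolute plateau tolerance (default 0.01).
#' @return the chosen K.
#' @export
select_plateau <- function(fractions, K = seq_along(fractions) + 1, eps = 0.01) {
  stopifnot(length(fractions) == length(K), length(K) >= 1, eps > 0,
            !is.unsorted(K, strictly = TRUE), all(is.finite(fractions)))
  if (length(K) >= 2) {
    for (i in seq_len(length(K) - 1)) {
      if (fractions[i] - fractions[i + 1] < eps) return(K[i])
    }
  }
  warning("no contralateral-fraction plateau within the scanned range; ",
          "returning K = ", K[length(K)])
  K[length(K)]
}

#' Scan model orders and choose one by the contralateral-fraction plateau
#'
#' Fits the mixture at every K in the range, selects each fit's stroke
#' component, computes its contralateral stroke fraction, and applies
#' [select_plateau()]. Failed fits are recorded and skipped.
#'
#' At each K two candidate solutions compete by log-likelihood on a common
#' seeded fitting subsample: a fresh k-means++-seeded EM fit, and a
#' greedy-insertion fit that warm-starts from the previous K's winner plus
#' one new component seeded where the previous model fits worst (candidate
#' insertion centers are found by clustering the lowest-density
#' observations). The insertion route is what lets the scan discover small,
#' rare clusters — such as a low-ADC artifact confined to a few hundred
#' voxels — that plain distance-based initialization essentially never
#' seeds, and which are precisely the clusters the contralateral fraction
#' is meant to expose.
#'
#' @param features normalized feature table (or matrix) of the pooled
#'   training cohort.
#' @param hemisphere per-observation hemisphere labels; defaults to the
#'   feature table's `hemisphere` column.
#' @param K_range model orders to scan (default 2:8).
#' @param eps plateau tolerance (default 0.01).
#' @param seed integer seed.
#' @param raw un-normalized features for component characterization (see
#'   [fit_gmm()]).
#' @param fit_subsample EM fitting subsample size (default 20000); the
#'   full dataset is always labeled exactly.
#' @param max_iter,tol,reg EM controls as in [fit_gmm()].
#' @param n_insert_candidates insertion centers tried per K (default 3).
#' @return object of class `model_order_scan`: `table` (K, fraction, init,
#'   converged, ok), `fits` (per-K `gmm_fit`s with stroke components set),
#'   `chosen_k`, `chosen_fit`, `eps`, `seed`.
#' @export
select_model_order <- function(features, hemisphere = NULL, K_range = 2:8,
                               eps = 0.01, seed = 1, raw = NULL,
                               fit_subsample = 20000,
                               max_iter = 500, tol = 1e-6, reg = 1e-6,
                               n_insert_candidates = 3) {
  stopifnot(length(K_range) >= 1, eps > 0)
  K_range <- sort(unique(as.integer(K_range)))
  if (is.null(hemisphere)) hemisphere <- features$hemisphere
  stopifnot(!is.null(hemisphere))
  x <- feature_matrix(features)
  xr <- if (is.null(raw)) x else feature_matrix(raw)
  stopifnot(length(hemisphere) == nrow(x))
  n <- nrow(x)
  xs <- if (!is.null(fit_subsample) && fit_subsample < n) {
    x[with_seed(derive_seed(seed, "subsample"), sample.int(n, fit_subsample)), ,
      drop = FALSE]
  } else x

  fits <- vector("list", length(K_range))
  frac <- rep(NA_real_, length(K_range))
  ok <- rep(FALSE, length(K_range))
  conv <- rep(NA, length(K_range))
  init <- rep(NA_character_, length(K_range))
  errors <- character(length(K_range))
  prev <- NULL
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    res <- tryCatch({
      kseed <- derive_seed(seed, paste0("K", K))
      par <- with_seed(kseed, suppressWarnings(
        em_gmm(xs, K, max_iter = max_iter, tol = tol, reg = reg)))
      used <- "kmeans++"
      if (!is.null(prev) && K == prev$K + 1) {
        ins <- with_seed(derive_seed(kseed, "insert"),
                         insertion_em(xs, prev$par, max_iter = max_iter,
                                      tol = tol, reg = reg,
                                      n_candidates = n_insert_candidates))
        if (!is.null(ins) && ins$loglik > par$loglik) {
          par <- ins
          used <- "insertion"
        }
      }
      if (!par$converged) {
        warning("EM did not converge within ", max_iter, " iterations (K = ",
                K, ")")
      }
      fit <- finish_gmm_fit(par, x, xr, K, kseed)
      fit$stroke_component <- select_stroke_component(fit)
      list(fit = fit, par = par, K = K, used = used,
           frac = contralateral_fraction(fit, hemisphere))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res$fit
      frac[i] <- res$frac
      conv[i] <- res$fit$converged
      init[i] <- res$used
      ok[i] <- TRUE
      prev <- res
    }
  }
  if (!any(ok)) stop("model-order scan failed at every K")
  chosen <- select_plateau(frac[ok], K_range[ok], eps)
  structure(list(table = data.frame(K = K_range, fraction = frac,
                                    init = init, converged = conv, ok = ok,
                                    error = errors),
                 fits = stats::setNames(fits, paste0("K", K_range)),
                 chosen_k = chosen,
                 chosen_fit = fits[[which(K_range == chosen)]],
                 eps = eps, seed = seed),
            class = "model_order_scan")
}

# Greedy component insertion: warm-start from a (K-1)-component solution and
# add one component seeded in the region the current model explains worst.
# Candidate centers come from k-means over the lowest-density observations,
# so a coherent blob of poorly-modeled voxels yields a candidate even when it
# is a tiny fraction of the data. Returns the best converged solution, or
# NULL if no candidate run beats nothing (never happens in practice).
insertion_em <- function(xs, prev_par, max_iter, tol, reg, n_candidates = 3,
                         screen_iters = 60) {
  dens <- mixture_logdens(xs, prev_par$weights, prev_par$means,
                          prev_par$covariances)
  n_worst <- min(max(50, round(0.01 * nrow(xs))), nrow(xs))
  worst <- xs[order(dens)[seq_len(n_worst)], , drop = FALSE]
  centers <- tryCatch(
    suppressWarnings(stats::kmeans(worst,
                                   centers = min(n_candidates,
                                                 nrow(unique(worst))),
                                   nstart = 3)$centers),
    error = function(e) worst[1, , drop = FALSE])
  S_new <- Reduce(`+`, prev_par$covariances) / length(prev_par$covariances) * 0.5
  best <- NULL
  for (c in seq_len(nrow(centers))) {
    w0 <- c(prev_par$weights * (1 - 0.005), 0.005)
    m0 <- rbind(prev_par$means, centers[c, ])
    S0 <- c(prev_par$covariances, list(S_new + diag(reg, 2)))
    cand <- em_run(xs, w0, m0, S0, max_iter = screen_iters, tol = tol, reg = reg)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (!is.null(best) && !best$converged) {
    best <- em_run(xs, best$weights, best$means, best$covariances,
                   max_iter = max_iter, tol = tol, reg = reg)
  }
  best
}

#' @export
print.model_order_scan <- function(x, ...) {
  cat("model_order_scan (eps =", x$eps, "): chosen K* =", x$chosen_k, "\n")
  print(x$table[, c("K", "fraction", "init", "converged", "ok")], row.names = FALSE)
  invisible(x)
}

#' Serialize a model-order scan to JSON
#'
#' @param scan a [select_model_order()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scan_json <- function(scan, path) {
  stopifnot(inherits(scan, "model_order_scan"))
  jsonlite::write_json(list(
    chosen_k = scan$chosen_k, eps = scan$eps, seed = scan$seed,
    scan = scan$table[, c("K", "fraction", "converged", "ok")],
    stroke_components = vapply(scan$fits, function(f)
      if (is.null(f)) NA_integer_ else f$stroke_component, integer(1))),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
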