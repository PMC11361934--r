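# Model-agnostic KernelSHAP.
#
# Shapley values are estimated by the kernel formulation: a coalition
# z in {0,1}^M keeps feature j at the explained instance's value when
# z_j = 1 and marginalizes it over a background sample when z_j = 0.  The
# coalition value is the mean model score over background rows with the
# coalition's features replaced; attributions solve the Shapley-kernel
# weighted least squares under the efficiency constraint
# sum(phi) = f(instance) - base_value, enforced by eliminating one unknown.

# Shapley kernel weight pi(z) = (M-1) / (choose(M,|z|) |z| (M-|z|))
.shapley_kernel <- function(M, k) {
  (M - 1) / (choose(M, k) * k * (M - k))
}

# coalition value function: rows = coalitions (0/1), returns mean masked score
.coalition_values <- function(score_fn, Z, instance, background) {
  nb <- nrow(background)
  n <- nrow(Z)
  M <- ncol(Z)
  big <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  mask <- Z[rep(seq_len(n), each = nb), , drop = FALSE] == 1
  inst <- matrix(instance, nrow(big), M, byrow = TRUE)
  big[mask] <- inst[mask]
  colnames(big) <- names(instance)
  v <- score_fn(big)
  rowMeans(matrix(v, nrow = n, byrow = TRUE))
}

# minimum-norm weighted least squares via SVD pseudo-inverse
.wls_minnorm <- function(A, t, w) {
  sw <- sqrt(w)
  Aw <- A * sw
  tw <- t * sw
  sv <- svd(Aw)
  pos <- sv$d > max(sv$d) * 1e-10
  as.vector(sv$v[, pos, drop = FALSE] %*%
              ((crossprod(sv$u[, pos, drop = FALSE], tw)) / sv$d[pos]))
}

#' KernelSHAP explanation of one instance
#'
#' @param score_fn Function taking a feature matrix (named columns matching
#'   `instance`) and returning a numeric score per row — typically
#'   `function(x) decision_scores(model, x)`.
#' @param instance Named numeric vector: the instance to explain.
#' @param background Feature matrix used as the reference distribution for
#'   marginalizing switched-off features.
#' @param n_samples Number of Monte Carlo coalitions (ignored when
#'   `method = "exact"`).
#' @param seed Integer seed for coalition sampling.
#' @param method `"sampling"` (default) draws `n_samples` coalitions with
#'   sizes weighted by the Shapley kernel; `"exact"` enumerates all
#'   `2^M - 2` proper coalitions with analytic kernel weights (feasible for
#'   small M).
#' @return A `shap_explanation`: `base_value` (mean background score),
#'   `phi` (one attribution per feature), `fx` (the instance's score).
#'   Efficiency `base_value + sum(phi) = fx` holds by construction.
#' @export
kernel_shap <- function(score_fn, instance, background, n_samples = 100L,
                        seed = 1L, method = c("sampling", "exact")) {
  method <- match.arg(method)
  M <- length(instance)
  if (M < 2L) stop("need at least 2 features to explain", call. = FALSE)
  stopifnot(is.matrix(background), nrow(background) >= 1L,
            identical(colnames(background), names(instance)))
  base_value <- mean(score_fn(background))
  fx <- as.numeric(score_fn(matrix(instance, 1,
                                   dimnames = list(NULL, names(instance)))))
  if (method == "exact") {
    ks <- unlist(lapply(1:(M - 1L), function(k) {
      rep(k, choose(M, k))
    }))
    Z <- matrix(0L, length(ks), M)
    row <- 1L
    for (k in 1:(M - 1L)) {
      sets <- utils::combn(M, k)
      for (j in seq_len(ncol(sets))) {
        Z[row, sets[, j]] <- 1L
        row <- row + 1L
      }
    }
    w <- .shapley_kernel(M, ks)
  } else {
    sizes <- 1:(M - 1L)
    size_p <- (M - 1) / (sizes * (M - sizes))
    Z <- with_seed(seed, {
      draw <- function() {
        k <- sample(sizes, 1L, prob = size_p)
        z <- integer(M)
        z[sample.int(M, k)] <- 1L
        z
      }
      t(replicate(n_samples, draw()))
    })
    if (nrow(unique(Z)) < 2L) {
      warning("degenerate coalition sample; resampling with a shifted seed",
              call. = FALSE)
      return(kernel_shap(score_fn, instance, background, n_samples,
                         seed + 1L, method))
    }
    w <- rep(1, nrow(Z))  # sampling frequency already follows the kernel
  }
  v <- .coalition_values(score_fn, Z, instance, background)
  # eliminate phi_M with the efficiency constraint
  A <- Z[, -M, drop = FALSE] - Z[, M]
  t_vec <- v - base_value - Z[, M] * (fx - base_value)
  phi_head <- .wls_minnorm(A, t_vec, w)
  phi <- c(phi_head, (fx - base_value) - sum(phi_head))
  names(phi) <- names(instance)
  structure(list(base_value = base_value, phi = phi, fx = fx,
                 n_samples = if (method == "exact") nrow(Z) else n_samples,
                 method = method, seed = seed),
            class = "shap_explanation")
}

#' Exact Shapley values by permutation averaging
#'
#' Direct evaluation of the classical Shapley formula: for each feature,
#' the coalition-size-weighted average of its marginal contributions over
#' all subsets of the remaining features.  Exponential in the number of
#' features; intended as an independent reference for small M.
#'
#' @inheritParams kernel_shap
#' @return Named numeric vector of Shapley values.
#' @export
shapley_exact <- function(score_fn, instance, background) {
  M <- length(instance)
  stopifnot(M >= 1L, M <= 16L)
  all_z <- as.matrix(expand.grid(rep(list(0:1), M)))
  colnames(all_z) <- NULL
  vals <- .coalition_values(score_fn, all_z, instance, background)
  key <- all_z %*% 2^(0:(M - 1))
  v_of <- function(z) vals[match(as.numeric(z %*% 2^(0:(M - 1))), key)]
  phi <- numeric(M)
  for (j in seq_len(M)) {
    others <- setdiff(seq_len(M), j)
    for (k in 0:(M - 1L)) {
      subsets <- if (k == 0L) {
        matrix(integer(0), 1, 0)
      } else {
        t(utils::combn(others, k))
      }
      weight <- factorial(k) * factorial(M - k - 1L) / factorial(M)
      for (r in seq_len(nrow(subsets))) {
        z <- integer(M)
        z[subsets[r, ]] <- 1L
        z_with <- z
        z_with[j] <- 1L
        phi[j] <- phi[j] + weight * (v_of(rbind(z_with)) - v_of(rbind(z)))
      }
    }
  }
  stats::setNames(phi, names(instance))
}

#' Explain a set of instances
#'
#' @param model A `trained_model`.
#' @param x Feature matrix of instances to explain (model contract order).
#' @param background Background feature matrix (reference distribution);
#'   typically a seeded subsample of the training matrix.
#' @param n_samples Monte Carlo coalitions per instance.
#' @param seed Base seed; instance `i` uses `seed + i`.
#' @return A `shap_explanations` object: list with `phi` (matrix, one row
#'   per instance), `base_value`, `fx`, and the configuration.
#' @export
shap_explain <- function(model, x, background, n_samples = 100L, seed = 1L) {
  .check_contract(model, x)
  score_fn <- function(m) decision_scores(model, m)
  out <- matrix(NA_real_, nrow(x), ncol(x),
                dimnames = list(NULL, colnames(x)))
  fx <- numeric(nrow(x))
  bv <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    ex <- kernel_shap(score_fn, x[i, ], background, n_samples = n_samples,
                      seed = seed + i)
    out[i, ] <- ex$phi
    fx[i] <- ex$fx
    bv[i] <- ex$base_value
  }
  structure(list(phi = out, base_value = bv, fx = fx,
                 n_samples = n_samples, seed = seed,
                 n_background = nrow(background)),
            class = "shap_explanations")
}

#' Global importance summary of SHAP explanations
#'
#' Ranks features by mean absolute attribution over the explained
#' instances, the usual summary-plot ordering.
#'
#' @param explanations A `shap_explanations` object, or a bare numeric
#'   matrix of per-instance attributions (columns = features).
#' @param top_k Number of top features to keep.
#' @return Data frame with columns `feature`, `mean_abs_shap`, `rank`,
#'   sorted by decreasing importance (ties broken by feature name).
#' @export
shap_summary <- function(explanations, top_k = 50L) {
  phi <- if (inherits(explanations, "shap_explanations")) {
    explanations$phi
  } else {
    explanations
  }
  stopifnot(is.matrix(phi), !is.null(colnames(phi)))
  imp <- colMeans(abs(phi))
  ord <- order(-imp, names(imp), method = "radix")  # locale-independent ties
  k <- min(top_k, length(imp))
  data.frame(feature = names(imp)[ord][seq_len(k)],
             mean_abs_shap = unname(imp[ord])[seq_len(k)],
             rank = seq_len(k),
             stringsAsFactors = FALSE)
}
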