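# Feature-matrix preprocessing: degenerate-column removal, train-fitted
# standardization, and correlation-based pruning.
#
# All parameters are fitted on the TRAINING matrix only and applied
# unchanged to test data, so no test information leaks into the model.

#' Drop zero-variance features
#'
#' Constant columns have undefined correlation and break unit-variance
#' scaling, so they are removed before the rest of the pipeline.  The
#' decision is made on the matrix given (the training matrix); apply the
#' returned column set to test data.
#'
#' @param x Numeric feature matrix with column names.
#' @return List with `x` (the reduced matrix) and `removed` (names of the
#'   dropped columns).
#' @export
drop_degenerate <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  v <- apply(x, 2, stats::var)
  degenerate <- v == 0 | !is.finite(v)
  if (all(degenerate)) stop("all features are degenerate", call. = FALSE)
  list(x = x[, !degenerate, drop = FALSE],
       removed = colnames(x)[degenerate])
}

#' Fit a standardizing scaler on training features
#'
#' Centers each feature to mean 0 and scales to unit variance (population
#' variance, i.e. divisor n), matching the usual preprocessing convention
#' for kernel methods.
#'
#' @param x Training feature matrix (degenerate columns removed).
#' @return A `scaler_params` object: per-feature means, standard deviations
#'   and the feature-name contract.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  if (any(s <= 0)) {
    stop("zero-variance feature(s); run drop_degenerate() first: ",
         paste(colnames(x)[s <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = m, sd = s, features = colnames(x)),
            class = "scaler_params")
}

#' Apply fitted scaler parameters
#'
#' @param params A `scaler_params` from [fit_scaler()] (fitted on train).
#' @param x Feature matrix to transform; must contain exactly the features
#'   of the contract, in any order.
#' @return Transformed matrix with columns in contract order.
#' @export
apply_scaler <- function(params, x) {
  stopifnot(inherits(params, "scaler_params"), is.matrix(x))
  missing <- setdiff(params$features, colnames(x))
  if (length(missing) > 0L) {
    stop("features missing at apply time: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- x[, params$features, drop = FALSE]
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}

#' Prune correlated features on the training matrix
#'
#' Computes pairwise Pearson correlations on the training matrix, walks the
#' feature pairs in lexicographic name order, and whenever both members of
#' a pair with `|r| > threshold` are still retained removes one of the two,
#' chosen by a seeded coin flip.  One pass suffices: any pair still intact
#' at the end was examined with both members retained and was below the
#' threshold.
#'
#' @param x Training feature matrix (degenerate columns removed).
#' @param threshold Absolute-correlation threshold above which a pair is
#'   considered redundant.
#' @param seed Integer seed for the removal coin flips.
#' @return A `prune_report`: `threshold`, `seed`, `retained` (feature
#'   names), and `removed` (data frame of removed feature and the retained
#'   partner that triggered the removal).
#' @export
prune_correlated <- function(x, threshold = 0.8, seed = 1L) {
  stopifnot(is.matrix(x), ncol(x) >= 1L, !is.null(colnames(x)))
  if (ncol(x) < 2L) {
    return(structure(list(threshold = threshold, seed = seed,
                          retained = colnames(x),
                          removed = data.frame(feature = character(0),
                                               partner = character(0))),
                     class = "prune_report"))
  }
  # radix sort = C-locale byte order, independent of the session locale,
  # so the pair enumeration (and hence the seeded removals) is reproducible
  feats <- sort(colnames(x), method = "radix")
  r <- stats::cor(x[, feats, drop = FALSE])
  p <- length(feats)
  keep <- rep(TRUE, p)
  removed <- character(0)
  partner <- character(0)
  with_seed(seed, {
    for (i in seq_len(p - 1L)) {
      if (!keep[i]) next
      for (j in seq((i + 1L), p)) {
        if (!keep[i]) break
        if (!keep[j]) next
        if (abs(r[i, j]) > threshold) {
          drop_first <- stats::runif(1) < 0.5
          victim <- if (drop_first) i else j
          survivor <- if (drop_first) j else i
          keep[victim] <- FALSE
          removed <- c(removed, feats[victim])
          partner <- c(partner, feats[survivor])
        }
      }
    }
  })
  structure(list(threshold = threshold, seed = seed,
                 retained = feats[keep],
                 removed = data.frame(feature = removed, partner = partner,
                                      stringsAsFactors = FALSE)),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("<prune_report> threshold=%.2f seed=%d retained=%d removed=%d\n",
              x$threshold, x$seed, length(x$retained), nrow(x$removed)))
  invisible(x)
}

#' Proxy groups implied by a prune report
#'
#' Pruning removes one member of each over-correlated pair, so a retained
#' feature stands proxy for the features removed on its account (and,
#' transitively, for their partners).  Returns, for every feature, the set
#' of features in its removal cluster; useful when asking whether a signal
#' planted on a removed feature surfaces through its retained proxy.
#'
#' @param report A `prune_report`.
#' @return Named list mapping each feature to the character vector of
#'   features in its cluster (every cluster contains the feature itself).
#' @export
prune_proxy_groups <- function(report) {
  stopifnot(inherits(report, "prune_report"))
  feats <- union(report$retained, report$removed$feature)
  parent <- stats::setNames(feats, feats)
  find <- function(f) {
    while (parent[[f]] != f) f <- parent[[f]]
    f
  }
  for (k in seq_len(nrow(report$removed))) {
    a <- find(report$removed$feature[k])
    b <- find(report$removed$partner[k])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(feats, find, character(1))
  clusters <- split(feats, roots)
  out <- lapply(roots, function(r) clusters[[r]])
  names(out) <- feats
  out
}

#' Fit the full preprocessing pipeline on training features
#'
#' Fixed composition: drop degenerate columns, prune correlated features at
#' `threshold`, then fit the standardizing scaler — all on the training
#' matrix only.
#'
#' @param x_train Training feature matrix.
#' @param threshold Correlation-pruning threshold.
#' @param seed Seed for the pruning coin flips.
#' @return A `feature_pipeline` holding the degenerate-column list, the
#'   `prune_report` and the `scaler_params`.
#' @export
fit_pipeline <- function(x_train, threshold = 0.8, seed = 1L) {
  dg <- drop_degenerate(x_train)
  pr <- prune_correlated(dg$x, threshold = threshold, seed = seed)
  xr <- dg$x[, pr$retained, drop = FALSE]
  sc <- fit_scaler(xr)
  structure(list(degenerate = dg$removed, prune = pr, scaler = sc),
            class = "feature_pipeline")
}

#' Apply a fitted preprocessing pipeline
#'
#' @param pipeline A `feature_pipeline` from [fit_pipeline()].
#' @param x Feature matrix (train or test).
#' @return Matrix restricted to the retained features and standardized with
#'   the train-fitted parameters.
#' @export
apply_pipeline <- function(pipeline, x) {
  stopifnot(inherits(pipeline, "feature_pipeline"))
  apply_scaler(pipeline$scaler, x)
}
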