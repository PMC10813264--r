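#' Fit the optic-flow-pattern template bank
#'
#' Trains the 18 statistical templates of the third level: nine temporal
#' windows per direction, window `j` covering frames `10(j-1)+1` to `10j` of
#' the 90-frame sequence (frame pairs are indexed by their ending frame, so
#' window 1 holds pairs 2..10 and the others 10 pairs each).  Each template
#' stores the pooled mean and diagonal dispersion of the opponent-motion
#' feature vectors over its window across all training sequences of its
#' direction.  Template order: right windows 1..9, then left windows 1..9.
#'
#' The instantaneous match is a diagonal-Gaussian class-conditional model
#' with a variance penalty ("risk aversion"); see [evidence_stream()].  This
#' classifier is a reconstruction: its contract is the monotonicity and
#' left/right symmetry of the evidence, not a specific closed form.
#'
#' @param features list of `n_pairs x D` feature matrices
#'   (from [sequence_features()]), one per training sequence.
#' @param directions character vector of labels, `"left"` or `"right"`,
#'   one per sequence.
#' @param n_windows number of temporal windows per direction (default 9).
#' @param var_floor lower bound applied to per-detector variances; `NULL`
#'   (default) floors at `(0.05 * rms)^2`, where `rms` is the root mean
#'   square of all training features, so windows with little motion do not
#'   become brittle near-delta templates.
#' @param lambda risk-aversion coefficient: weight of the extra dispersion
#'   penalty added to the Gaussian log-likelihood.
#' @param evidence_range target range `(lo, hi)` of the affine evidence
#'   rescaling: the training mean of the per-frame best match maps to the top
#'   of the range and the grand mean of all matches to the bottom.  One
#'   common mapping is derived at fit time and stored in the bank, so
#'   between-template evidence differences keep their relative scale.
#' @return object of class `template_bank`.
#' @export
fit_templates <- function(features, directions, n_windows = 9L,
                          var_floor = NULL, lambda = 0.1,
                          evidence_range = c(0, 1)) {
  stopifnot(length(features) == length(directions),
            all(directions %in% c("left", "right")))
  if (min(table(factor(directions, c("left", "right")))) < 2)
    stop("need at least 2 training sequences per direction")
  np <- nrow(features[[1]])
  if (any(vapply(features, nrow, 1L) != np))
    stop("training sequences must share the same frame count")
  D <- ncol(features[[1]])
  if (is.null(var_floor))
    var_floor <- (0.05 * sqrt(mean(unlist(features)^2)))^2
  var_floor <- max(var_floor, 1e-12)
  frames_per <- (np + 1) / n_windows          # 10 under the default protocol
  pair_window <- pmin(n_windows, ceiling((2:(np + 1)) / frames_per))

  templates <- list()
  for (dir in c("right", "left")) {
    rows_dir <- which(directions == dir)
    for (w in seq_len(n_windows)) {
      X <- do.call(rbind, lapply(features[rows_dir],
                                 function(f) f[pair_window == w, , drop = FALSE]))
      mu <- colMeans(X)
      s2 <- pmax(apply(X, 2, stats::var), var_floor)
      templates[[length(templates) + 1]] <-
        list(direction = dir, window = w, mu = mu, sigma2 = s2)
    }
  }
  nt <- length(templates)
  bank <- structure(list(templates = templates, D = D, n_windows = n_windows,
                         lambda = lambda, var_floor = var_floor,
                         pair_window = pair_window,
                         scale = list(gain = rep(1, nt), offset = rep(0, nt)),
                         evidence_range = evidence_range),
                    class = "template_bank")
  # common affine rescaling (see evidence_range above)
  raw <- do.call(rbind, lapply(features, raw_evidence, bank = bank))
  top <- mean(apply(raw, 1, max))
  base <- mean(raw)
  if (top - base < 1e-12) top <- base + 1     # degenerate training set
  gain <- diff(evidence_range) / (top - base)
  bank$scale <- list(gain = rep(gain, nt),
                     offset = rep(evidence_range[1] - base * gain, nt))
  bank
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("Template bank: %d templates (%d windows x 2 directions), D = %d, lambda = %g\n",
              length(x$templates), x$n_windows, x$D, x$lambda))
  invisible(x)
}

# unscaled per-dimension-averaged Gaussian log-likelihood minus the
# risk-aversion dispersion penalty; feature may be a matrix (rows = frames)
raw_evidence <- function(feature, bank) {
  if (is.null(dim(feature))) feature <- matrix(feature, 1)
  if (ncol(feature) != bank$D) stop("feature dimension does not match bank")
  out <- matrix(NA_real_, nrow(feature), length(bank$templates))
  for (i in seq_along(bank$templates)) {
    tp <- bank$templates[[i]]
    quad <- as.vector(sweep(feature, 2, tp$mu)^2 %*% (1 / tp$sigma2)) / bank$D
    const <- mean(log(2 * pi * tp$sigma2))
    risk <- 0.5 * mean(log(tp$sigma2))
    out[, i] <- -0.5 * (const + quad) - bank$lambda * risk
  }
  out
}

#' Feed-forward evidence for one feature vector
#'
#' Risk-averse Gaussian match of a single opponent-motion feature vector
#' against all 18 templates, affinely rescaled to the bank's evidence range.
#' With `lambda = 0` the ranking reduces to the pure log-likelihood.
#'
#' @param feature numeric vector of length `D`.
#' @param bank a [fit_templates()] bank.
#' @return numeric vector of 18 evidence values, ordered as the bank's
#'   templates (right windows 1..9, left windows 1..9).
#' @export
template_evidence <- function(feature, bank) {
  as.vector(raw_evidence(feature, bank)) * bank$scale$gain + bank$scale$offset
}

apply_scale <- function(raw, bank) {
  sweep(sweep(raw, 2, bank$scale$gain, "*"), 2, bank$scale$offset, "+")
}

#' Evidence time series for a whole sequence
#'
#' @param features `n_pairs x D` feature matrix of one sequence.
#' @param bank a `template_bank`.
#' @return `n_pairs x 18` matrix of rescaled evidence values `G_i`.
#' @export
evidence_stream <- function(features, bank) {
  apply_scale(raw_evidence(features, bank), bank)
}

#' k-fold cross-validated direction classification
#'
#' Splits the labelled sequences into `k` folds, refits the template bank on
#' each training split and classifies each held-out sequence by the direction
#' whose nine templates collect the larger total evidence.
#'
#' @param features list of feature matrices.
#' @param directions labels.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param ... passed on to [fit_templates()].
#' @return list with per-fold accuracies, their mean and sd, and the fold
#'   assignment.
#' @export
crossvalidate_templates <- function(features, directions, k = 5L, seed = 1L,
                                    ...) {
  n <- length(features)
  stopifnot(n >= k)
  fold <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  })
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(directions[tr])) < 2)
      stop("fold with a single class; use more sequences or fewer folds")
    bank <- fit_templates(features[tr], directions[tr], ...)
    dirs <- vapply(bank$templates, `[[`, "", "direction")
    pred <- vapply(te, function(i) {
      ev <- colSums(evidence_stream(features[[i]], bank))
      c("right", "left")[which.max(c(sum(ev[dirs == "right"]),
                                     sum(ev[dirs == "left"])))]
    }, "")
    acc[f] <- mean(pred == directions[te])
  }
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc), fold = fold)
}
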