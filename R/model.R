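# bipolar 2-bit nucleotide encoding: A {1,1}, C {-1,1}, U {1,-1}, G {-1,-1}
NUC_CODE <- rbind(A = c(1, 1), C = c(-1, 1), G = c(-1, -1), T = c(1, -1))

#' Encode a stop-codon context as a bipolar feature vector
#'
#' Each selected position contributes two entries in \{-1, +1\}:
#' A -> (1, 1), C -> (-1, 1), U -> (1, -1), G -> (-1, -1); an intercept
#' entry of 1 is prepended, so the vector has length
#' `2 * length(positions) + 1`.
#'
#' @param context a 70-nt context string.
#' @param positions integer vector of selected position labels (negative
#'   upstream of the stop codon, positive downstream; stop-codon slots are
#'   not encodable).
#' @return named numeric vector: `(Intercept)` followed by two features per
#'   position (suffixes `.1`, `.2`).
#' @examples
#' encode_context(strrep("A", 70), c(-2, 1))
#' @export
encode_context <- function(context, positions) {
  idx <- scc_label_to_index(positions)
  bases <- seq_chars(normalize_seq(context))[idx]
  if (anyNA(bases) || !all(bases %in% NUCLEOTIDES)) {
    stop("context contains a non-ACGU/T symbol at a selected position")
  }
  v <- c(1, as.vector(t(NUC_CODE[bases, , drop = FALSE])))
  names(v) <- c("(Intercept)",
                paste0("pos", rep(positions, each = 2), c(".1", ".2")))
  v
}

#' Decode a bipolar feature vector back to nucleotides
#'
#' Inverse of [encode_context()] at the selected positions.
#'
#' @param v feature vector as returned by [encode_context()].
#' @return character vector of nucleotides, one per encoded position.
#' @export
decode_features <- function(v) {
  stopifnot(length(v) %% 2L == 1L)
  pairs <- matrix(v[-1L], nrow = 2L)
  key <- paste(NUC_CODE[, 1], NUC_CODE[, 2])
  rownames(NUC_CODE)[match(paste(pairs[1L, ], pairs[2L, ]), key)]
}

#' Select the most informative context positions by divergence
#'
#' Returns the `k` positions with the largest single-position divergence.
#' Ties are broken in favour of the position closer to the stop codon
#' (smaller absolute label); the result is ordered 5' to 3'.
#'
#' @param divergence either the `per_position` data.frame from
#'   [scc_divergence()] or a numeric vector of divergences named by
#'   position label.
#' @param k number of positions to select.
#' @return integer vector of `k` position labels in 5' to 3' order.
#' @export
select_positions <- function(divergence, k) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  if (is.data.frame(divergence)) {
    keep <- !is.na(divergence$label)
    lab <- divergence$label[keep]
    D <- divergence$D[keep]
  } else {
    lab <- as.integer(names(divergence))
    D <- as.numeric(divergence)
  }
  if (k > length(lab)) stop("k exceeds the number of eligible positions")
  ord <- order(-D, abs(lab), lab)
  sort(lab[ord][seq_len(k)])
}

#' Build the regression design of a training set
#'
#' Following the convention of the estimation procedure, the design `X` has
#' one column per training sequence and one row per feature (the intercept
#' row of ones first, then two rows per selected position).
#'
#' @param contexts character vector of 70-nt context sequences (length M).
#' @param rates numeric vector of M leak rates.
#' @param positions selected position labels.
#' @return list with `X` (N x M feature matrix) and `y` (length-M rates).
#' @export
build_design <- function(contexts, rates, positions) {
  if (length(contexts) != length(rates)) {
    stop("contexts and rates differ in length")
  }
  if (length(contexts) < 1L) stop("empty training set")
  X <- vapply(contexts, encode_context, positions = positions,
              numeric(2L * length(positions) + 1L), USE.NAMES = FALSE)
  rownames(X) <- names(encode_context(contexts[1L], positions))
  list(X = X, y = as.numeric(rates))
}

#' Minimum-norm least-squares fit via SVD
#'
#' Solves `min ||t(X) w - y||` and, among all least-squares solutions,
#' returns the one with the smallest Euclidean norm, computed from the
#' singular value decomposition of the transposed design. Singular values
#' below `tol` times the largest are treated as zero (pseudoinverse
#' truncation), which makes rank-deficient designs well-defined.
#'
#' @param X N x M feature matrix (features in rows, sequences in columns).
#' @param y length-M response vector.
#' @param tol relative singular-value truncation threshold.
#' @return list with `w` (length-N coefficients), `singular_values`
#'   (nonincreasing), and `rank` (number of retained singular values).
#' @export
fit_min_norm <- function(X, y, tol = 1e-10) {
  stopifnot(is.matrix(X), ncol(X) == length(y))
  A <- t(X)  # M x N: rows are training sequences
  sv <- svd(A)
  d <- sv$d
  keep <- d > tol * max(d, 0)
  w <- if (!any(keep)) {
    numeric(nrow(X))
  } else {
    sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / d[keep])
  }
  w <- as.numeric(w)
  names(w) <- rownames(X)
  list(w = w, singular_values = d, rank = sum(keep))
}

#' Fit a linear leak-rate model on stop-codon contexts
#'
#' The central fitting function: encodes each training context at the
#' selected positions with the bipolar two-bit code, assembles the design,
#' and estimates the coefficients `w = (a0, b)` of
#' `rate = a0 + sum_i b_i x_i` by minimum-norm least squares (SVD
#' pseudoinverse). The sign of a prediction is read as presence (positive)
#' or absence (zero or negative) of readthrough.
#'
#' @param contexts character vector of 70-nt training contexts.
#' @param rates numeric vector of observed leak rates, one per context.
#' @param positions selected position labels (e.g. from
#'   [select_positions()] or [model_variants()]).
#' @param stop_codon optional stop-codon label (UAA/UAG/UGA) recorded in the
#'   model; models are meant to be fitted per stop codon.
#' @param tol singular-value truncation tolerance (see [fit_min_norm()]).
#' @return an object of class `"leak_model"` with components
#'   `coefficients`, `positions`, `stop_codon`, `singular_values`, `rank`,
#'   `M` (training size), `tol`, `fitted.values`, `residuals`, `sigma`.
#' @seealso [predict.leak_model()], [evaluate_leak_model()],
#'   [model_variants()]
#' @examples
#' set.seed(1)
#' ctx <- replicate(40, paste(sample(c("A","C","G","T"), 70, TRUE), collapse = ""))
#' ctx <- paste0(substr(ctx, 1, 49), "TGA", substr(ctx, 53, 70))
#' rates <- runif(40, 0, 0.05)
#' fit <- leak_model(ctx, rates, positions = c(-2, -1, 1, 2))
#' coef(fit)
#' @export
leak_model <- function(contexts, rates, positions, stop_codon = NA_character_,
                       tol = 1e-10) {
  d <- build_design(contexts, rates, positions)
  fit <- fit_min_norm(d$X, d$y, tol = tol)
  fitted <- as.numeric(crossprod(d$X, fit$w))
  res <- d$y - fitted
  df_res <- max(length(d$y) - fit$rank, 1L)
  obj <- list(coefficients = fit$w, positions = as.integer(positions),
              stop_codon = stop_codon,
              singular_values = fit$singular_values, rank = fit$rank,
              M = length(d$y), tol = tol,
              fitted.values = fitted, residuals = res,
              sigma = sqrt(sum(res^2) / df_res),
              call = match.call())
  class(obj) <- "leak_model"
  obj
}

#' @export
print.leak_model <- function(x, ...) {
  cat("Linear leak-rate model",
      if (!is.na(x$stop_codon)) sprintf("(%s)", x$stop_codon), "\n")
  cat(sprintf("  %d positions, %d coefficients, M = %d training contexts, rank %d\n",
              length(x$positions), length(x$coefficients), x$M, x$rank))
  cat("  positions:", paste(sprintf("%+d", x$positions), collapse = " "), "\n")
  cat(sprintf("  intercept a0 = %.4g, residual sd = %.4g\n",
              x$coefficients[1L], x$sigma))
  invisible(x)
}

#' @export
coef.leak_model <- function(object, ...) object$coefficients

#' @export
residuals.leak_model <- function(object, ...) object$residuals

#' @export
fitted.leak_model <- function(object, ...) object$fitted.values

#' @export
summary.leak_model <- function(object, ...) {
  co <- object$coefficients[-1L]
  per_pos <- matrix(co, nrow = 2L)
  tab <- data.frame(position = object$positions,
                    b1 = per_pos[1L, ], b2 = per_pos[2L, ])
  out <- list(model = object, coefficients = tab,
              sv_range = range(object$singular_values))
  class(out) <- "summary.leak_model"
  out
}

#' @export
print.summary.leak_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  singular values in [%.4g, %.4g]\n",
              x$sv_range[1L], x$sv_range[2L]))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Predict leak rates for new contexts
#'
#' Computes `w . v` for each context's feature vector `v`. Predictions may
#' be negative; a nonpositive value is interpreted as "no readthrough".
#'
#' @param object a fitted [leak_model()].
#' @param newdata character vector of 70-nt contexts; if missing, fitted
#'   values are returned.
#' @param ... unused.
#' @return numeric vector of predicted leak rates.
#' @export
predict.leak_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  vapply(newdata, function(ctx) {
    sum(object$coefficients * encode_context(ctx, object$positions))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
simulate.leak_model <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted.values else
    predict(object, newdata)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' False-positive / false-negative evaluation of a leak model
#'
#' A false positive is a context without readthrough for which the model
#' predicts a strictly positive leak rate; a false negative is a
#' readthrough context for which it predicts a strictly negative rate (a
#' prediction of exactly zero is "no readthrough predicted", hence counted
#' neither way).
#'
#' @param model a fitted [leak_model()].
#' @param positives character vector of contexts with readthrough (held out
#'   of training).
#' @param negatives character vector of contexts without readthrough.
#' @return object of class `"leak_eval"`: list with `fp_fraction`,
#'   `fn_fraction`, `fp_count`, `fn_count`, `n_positives`, `n_negatives`.
#' @export
evaluate_leak_model <- function(model, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both test sets must be nonempty")
  }
  pred_pos <- predict(model, positives)
  pred_neg <- predict(model, negatives)
  out <- list(fp_count = sum(pred_neg > 0), fn_count = sum(pred_pos < 0),
              n_positives = length(positives), n_negatives = length(negatives))
  out$fp_fraction <- out$fp_count / out$n_negatives
  out$fn_fraction <- out$fn_count / out$n_positives
  class(out) <- "leak_eval"
  out
}

#' @export
print.leak_eval <- function(x, ...) {
  cat(sprintf("false positives: %d/%d (%.1f%%)  false negatives: %d/%d (%.1f%%)\n",
              x$fp_count, x$n_negatives, 100 * x$fp_fraction,
              x$fn_count, x$n_positives, 100 * x$fn_fraction))
  invisible(x)
}

#' The three canonical position sets for model comparison
#'
#' Returns the position sets of the three model variants compared in the
#' analysis: (a) `flank12` -- the six positions on each side of the stop
#' codon (the short-context model of earlier work); (b) `contig29` -- 29
#' positions contiguous to the stop codon (default split: 15 upstream, 14
#' downstream; the downstream flank of the analysis window caps the
#' downstream share at 18); (c) `topk` -- the k most informative positions
#' by divergence, with k defaulting to 18 (UGA), 13 (UAA) or 25 (UAG).
#'
#' @param stop_codon `"UGA"`, `"UAA"` or `"UAG"` (sets the default k).
#' @param divergence divergence profile for the `topk` variant (see
#'   [select_positions()]); may be `NULL`, in which case `topk` is omitted.
#' @param k number of divergence-selected positions (default per codon).
#' @param contig29_split length-2 integer: upstream/downstream position
#'   counts of the contiguous variant (must sum to 29, downstream at most 18).
#' @return named list of position-label vectors: `flank12`, `contig29`, and
#'   (when a divergence profile is given) `topk`.
#' @export
model_variants <- function(stop_codon = c("UGA", "UAA", "UAG"),
                           divergence = NULL, k = NULL,
                           contig29_split = c(15L, 14L)) {
  stop_codon <- match.arg(stop_codon)
  if (is.null(k)) {
    k <- c(UGA = 18L, UAA = 13L, UAG = 25L)[[stop_codon]]
  }
  stopifnot(sum(contig29_split) == 29L, contig29_split[2L] <= SCC_DOWN,
            contig29_split[1L] <= SCC_UP)
  out <- list(
    flank12 = c(-6:-1, 1:6),
    contig29 = c(seq.int(-contig29_split[1L], -1L),
                 seq_len(contig29_split[2L])))
  if (!is.null(divergence)) {
    out$topk <- select_positions(divergence, k)
  }
  out
}
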