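# HAYSTACK-style expression-model matching: decide per transcript whether
# its tissue profile matches the bait gene's model under four criteria
# (correlation, background, fold change, p-value).

#' Pearson correlation between two expression vectors
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the Pearson product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 tissues", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Expression fold change and background
#'
#' `background` is the maximum abundance across tissues. `fold` is the
#' maximum divided by the minimum, with the denominator floored to protect
#' against zero or near-zero tissue values (models measured in RPM can
#' contain entries like 0.01 that would otherwise give unstable folds).
#'
#' @param v non-negative expression vector.
#' @param floor denominator floor (default 1, the background cutoff).
#' @return list with `fold` and `background`; `fold` is `NA` for an
#'   all-zero vector.
#' @export
#' @examples
#' fold_and_background(c(0.01, 33.3, 140))  # fold 140
fold_and_background <- function(v, floor = 1) {
  if (any(v < 0)) stop("negative expression values", call. = FALSE)
  bg <- max(v)
  fold <- if (bg == 0) NA_real_ else bg / max(min(v), floor)
  list(fold = fold, background = bg)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Parametric t-test on r: t = r * sqrt((n - 2) / (1 - r^2)) with n - 2
#' degrees of freedom. With three tissues (df = 1) the p <= 0.05 criterion
#' requires |r| >= 0.9969, which dominates the 0.8 correlation cutoff.
#'
#' @param r correlation in [-1, 1].
#' @param n_tissues number of paired observations (>= 3).
#' @return two-sided p-value (0 at |r| = 1).
#' @export
correlation_pvalue <- function(r, n_tissues) {
  if (n_tissues < 3) stop("need at least 3 tissues", call. = FALSE)
  if (abs(r) > 1 + 1e-12) stop("r outside [-1, 1]", call. = FALSE)
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n_tissues - 2) / (1 - r^2))
  2 * stats::pt(abs(t_stat), df = n_tissues - 2, lower.tail = FALSE)
}

#' Matching criteria for the expression screen
#'
#' Defaults are the published screening thresholds: correlation >= 0.8,
#' background >= 1, fold change >= 4, p-value <= 0.05.
#'
#' @param corr_cutoff minimum Pearson r (in [-1, 1]).
#' @param background_cutoff minimum peak abundance (> 0).
#' @param fold_cutoff minimum max/min fold change (> 0).
#' @param p_cutoff maximum correlation p-value (> 0).
#' @param use_p apply the p-value criterion (default TRUE).
#' @param log_transform correlate log2(x + 1)-transformed profiles instead
#'   of raw abundances (default FALSE). Fold and background always use
#'   raw values.
#' @return object of class `match_criteria`.
#' @export
match_criteria <- function(corr_cutoff = 0.8, background_cutoff = 1,
                           fold_cutoff = 4, p_cutoff = 0.05,
                           use_p = TRUE, log_transform = FALSE) {
  if (corr_cutoff < -1 || corr_cutoff > 1) {
    stop("corr_cutoff must be in [-1, 1]", call. = FALSE)
  }
  if (background_cutoff <= 0 || fold_cutoff <= 0 || p_cutoff <= 0) {
    stop("background, fold and p cutoffs must be positive", call. = FALSE)
  }
  structure(list(corr_cutoff = corr_cutoff,
                 background_cutoff = background_cutoff,
                 fold_cutoff = fold_cutoff, p_cutoff = p_cutoff,
                 use_p = isTRUE(use_p), log_transform = isTRUE(log_transform)),
            class = "match_criteria")
}

#' Bait expression model
#'
#' The per-assembly tissue expression profile of the bait gene, against
#' which candidate transcripts are matched.
#'
#' @param assembly_id assembly label.
#' @param values non-negative model vector, one value per tissue, not all
#'   equal.
#' @param tissues tissue labels (default leaf, inflorescence, bulb).
#' @param unit abundance unit tag (`"relative"`, `"RPM"` or `"TPM"`);
#'   informational.
#' @param bait_transcript_id optional id of the bait's own transcript in
#'   the assembly (excluded from its passing list).
#' @return object of class `bait_model`.
#' @export
bait_model <- function(assembly_id, values,
                       tissues = c("leaf", "inflorescence", "bulb"),
                       unit = "relative", bait_transcript_id = NULL) {
  values <- as.numeric(values)
  if (length(values) != length(tissues)) {
    stop("model length must equal tissue count", call. = FALSE)
  }
  if (any(values < 0)) stop("model values must be >= 0", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("model values must not all be equal", call. = FALSE)
  }
  structure(list(assembly_id = assembly_id,
                 tissues = as.character(tissues),
                 values = setNames(values, tissues), unit = unit,
                 bait_transcript_id = bait_transcript_id),
            class = "bait_model")
}

#' @export
print.bait_model <- function(x, ...) {
  cat(sprintf("bait_model '%s' (%s): %s\n", x$assembly_id, x$unit,
              paste(sprintf("%s=%g", x$tissues, x$values), collapse = ", ")))
  invisible(x)
}

#' Match one expression vector against a bait model
#'
#' A transcript matches when all enabled criteria hold:
#' r >= `corr_cutoff`, background >= `background_cutoff`,
#' fold >= `fold_cutoff`, and (when `use_p`) p <= `p_cutoff`. Degenerate
#' vectors (constant or all zero) never match and are flagged.
#'
#' @param v expression vector aligned to the bait tissue order.
#' @param bait a [bait_model()].
#' @param criteria a [match_criteria()].
#' @param transcript_id label carried into the result.
#' @return one-row data.frame with columns `transcript_id`, `r`, `fold`,
#'   `background`, `p`, `passed`, `failed_criteria` (comma-separated).
#' @export
model_match <- function(v, bait, criteria = match_criteria(),
                        transcript_id = NA_character_) {
  stopifnot(inherits(bait, "bait_model"), inherits(criteria, "match_criteria"))
  if (length(v) != length(bait$values)) {
    stop("expression vector not aligned to bait tissues", call. = FALSE)
  }
  fb <- fold_and_background(v, floor = criteria$background_cutoff)
  model <- bait$values
  cv <- v
  cm <- model
  if (criteria$log_transform) {
    cv <- log2(cv + 1)
    cm <- log2(cm + 1)
  }
  r <- tryCatch(pearson_r(cv, cm), error = function(e) NA_real_)
  p <- if (is.na(r)) NA_real_ else correlation_pvalue(r, length(v))
  failed <- character()
  if (is.na(r)) {
    failed <- c(failed, "degenerate")
  } else {
    if (r < criteria$corr_cutoff) failed <- c(failed, "correlation")
    if (criteria$use_p && p > criteria$p_cutoff) failed <- c(failed, "p")
  }
  if (fb$background < criteria$background_cutoff) {
    failed <- c(failed, "background")
  }
  if (is.na(fb$fold) || fb$fold < criteria$fold_cutoff) {
    failed <- c(failed, "fold")
  }
  data.frame(transcript_id = transcript_id, r = r, fold = fb$fold,
             background = fb$background, p = p,
             passed = length(failed) == 0L,
             failed_criteria = paste(failed, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Screen a whole expression matrix against a bait model
#'
#' Applies [model_match()] to every transcript of an assembly. The bait's
#' own transcript (when named in the model) is excluded: its self-match is
#' trivially perfect.
#'
#' @param mat an [expression_matrix()].
#' @param bait a [bait_model()]; its tissues must be a subset of the
#'   matrix tissues.
#' @param criteria a [match_criteria()].
#' @param all return every transcript's result (`TRUE`) or only the
#'   passing set (`FALSE`, default). Rows are sorted by transcript id.
#' @return data.frame of match results.
#' @export
screen_matrix <- function(mat, bait, criteria = match_criteria(),
                          all = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(bait, "bait_model"))
  if (!all(bait$tissues %in% mat$tissues)) {
    stop("bait tissues not all present in expression matrix", call. = FALSE)
  }
  vals <- mat$values[, bait$tissues, drop = FALSE]
  ids <- rownames(vals)
  keep <- if (is.null(bait$bait_transcript_id)) rep(TRUE, length(ids)) else
            ids != bait$bait_transcript_id
  ids <- sort(ids[keep])
  rows <- lapply(ids, function(id) {
    model_match(vals[id, ], bait, criteria, transcript_id = id)
  })
  out <- if (length(rows) == 0) {
    model_match(bait$values + 1, bait, criteria)[0, ]
  } else {
    do.call(rbind, rows)
  }
  if (!all) out <- out[out$passed, , drop = FALSE]
  rownames(out) <- NULL
  out
}
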