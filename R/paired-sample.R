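#' Paired measurements from two methods
#'
#' Container for a method-comparison data set: each subject measured by two
#' methods X and Y, possibly with several replicate measurements per method
#' (wide/unstacked format, one column per replicate).  Subjects with any
#' missing replicate on either method are dropped, with the count reported,
#' because the paired analysis needs complete pairs.
#'
#' @param x,y measurements for method X and Y: numeric vectors (one
#'   replicate) or matrices/data frames with one row per subject and one
#'   column per replicate.
#' @param subject_ids optional subject identifiers; defaults to 1..n.
#' @param method_names length-2 character vector labelling the methods;
#'   default `c("X", "Y")`.
#' @return A `"paired_sample"`: list with matrices `x`, `y` (rows =
#'   subjects), `subject_ids`, `method_names`, and `n_dropped`.
#' @examples
#' paired_sample(c(4.1, 3.9, 4.4), c(4.0, 4.0, 4.3))
#' @export
paired_sample <- function(x, y, subject_ids = NULL,
                          method_names = c("X", "Y")) {
  x <- as_replicate_matrix(x, "x")
  y <- as_replicate_matrix(y, "y")
  if (nrow(x) != nrow(y))
    stop("methods X and Y must have the same number of subjects",
         call. = FALSE)
  if (nrow(x) == 0L)
    stop("no subjects provided", call. = FALSE)
  if (!is.character(method_names) || length(method_names) != 2L)
    stop("`method_names` must be two labels", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(x))
  if (length(subject_ids) != nrow(x))
    stop("`subject_ids` length must equal the subject count", call. = FALSE)

  complete <- stats::complete.cases(x) & stats::complete.cases(y)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped for missing replicates")
    x <- x[complete, , drop = FALSE]
    y <- y[complete, , drop = FALSE]
    subject_ids <- subject_ids[complete]
  }
  if (nrow(x) < 2L)
    stop("fewer than 2 complete subjects remain", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("measurements must be finite", call. = FALSE)

  structure(list(x = x, y = y, subject_ids = subject_ids,
                 method_names = method_names,
                 n_dropped = as.integer(n_dropped)),
            class = "paired_sample")
}

as_replicate_matrix <- function(v, what) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.vector(v) && is.numeric(v)) v <- matrix(v, ncol = 1)
  if (!is.matrix(v) || !is.numeric(v))
    stop("`", what, "` must be a numeric vector, matrix or data frame",
         call. = FALSE)
  v
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("Paired sample: %d subjects, %s (%d repl.) vs %s (%d repl.)\n",
              nrow(x$x), x$method_names[1], ncol(x$x),
              x$method_names[2], ncol(x$y)))
  invisible(x)
}

#' Read paired measurements from a delimited text file
#'
#' Reads a wide-format CSV/TSV (one row per subject) and extracts the
#' replicate columns of each method by name or numeric position.  The
#' delimiter is sniffed among comma, tab and semicolon.
#'
#' @param path file path.
#' @param x_cols,y_cols column names (character) or positions (numeric) of
#'   the X and Y replicate columns.
#' @param id_col optional column holding subject identifiers.
#' @param method_names labels for the two methods; defaults to the first
#'   column name of each side.
#' @return A [paired_sample()].
#' @export
read_paired_csv <- function(path, x_cols, y_cols, id_col = NULL,
                            method_names = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- names(which.max(vapply(
    c("," = ",", "\t" = "\t", ";" = ";"),
    function(s) lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))),
    integer(1))))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cols, side) {
    if (is.character(cols)) {
      missing_cols <- setdiff(cols, names(df))
      if (length(missing_cols))
        stop("column(s) not found for ", side, ": ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      sub <- df[cols]
    } else {
      if (any(cols < 1 | cols > ncol(df)))
        stop("column position out of range for ", side, call. = FALSE)
      sub <- df[cols]
    }
    for (j in seq_along(sub)) {
      v <- sub[[j]]
      if (!is.numeric(v)) {
        conv <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
        if (length(bad))
          stop(sprintf("non-numeric value in column '%s', row %d",
                       names(sub)[j], bad[1]), call. = FALSE)
        sub[[j]] <- conv
      }
    }
    as.matrix(sub)
  }
  xm <- pick(x_cols, "x")
  ym <- pick(y_cols, "y")
  ids <- if (!is.null(id_col)) df[[id_col]] else seq_len(nrow(df))
  if (is.null(method_names))
    method_names <- c(colnames(xm)[1], colnames(ym)[1])
  paired_sample(xm, ym, subject_ids = ids, method_names = method_names)
}

#' Generate a synthetic paired sample
#'
#' Manufactures a method-comparison data set: each subject has a true value
#' drawn around `base_level`; method Y reports the truth, method X the
#' truth plus a systematic bias and Gaussian noise, so the differences
#' X - Y are Normal(`true_bias`, `sd_diff`).
#'
#' @param n number of subjects, >= 2.
#' @param true_bias systematic difference between the methods.
#' @param sd_diff standard deviation of the differences, >= 0.
#' @param base_level centre of the true values; default 5.
#' @param base_sd spread of the true values across subjects; default 1.
#' @param seed integer seed; the sample is deterministic given the seed.
#' @return A [paired_sample()].
#' @examples
#' generate_paired_fixture(20, true_bias = -0.012, sd_diff = 0.047, seed = 3)
#' @export
generate_paired_fixture <- function(n, true_bias = 0, sd_diff = 1,
                                    base_level = 5, base_sd = 1, seed = 1L) {
  check_n(n)
  if (sd_diff < 0) stop("`sd_diff` must be >= 0", call. = FALSE)
  old <- local_rng_seed(seed)
  on.exit(restore_rng_seed(old), add = TRUE)
  truth <- stats::rnorm(n, base_level, base_sd)
  d <- true_bias + stats::rnorm(n, 0, sd_diff)
  paired_sample(truth + d, truth)
}

#' Calibrate a paired sample to exact difference statistics
#'
#' Affinely rescales the difference component of a single-replicate paired
#' sample so the differences X - Y have exactly the requested mean and
#' standard deviation (divisor n - 1).  Useful for reproducing a published
#' analysis from its printed summary statistics when the raw data are not
#' available.  The per-subject means are preserved up to the implied shift.
#'
#' @param sample a single-replicate [paired_sample()].
#' @param target_mean desired mean difference.
#' @param target_sd desired SD of the differences, > 0.
#' @return A [paired_sample()] whose differences match the targets exactly.
#' @examples
#' s <- generate_paired_fixture(20, seed = 3)
#' s20 <- calibrate_to_summary(s, -0.012, 0.047)
#' summarize_diffs(s20$x[, 1] - s20$y[, 1])
#' @export
calibrate_to_summary <- function(sample, target_mean, target_sd) {
  if (!inherits(sample, "paired_sample"))
    stop("`sample` must be a `paired_sample`", call. = FALSE)
  if (ncol(sample$x) != 1L || ncol(sample$y) != 1L)
    stop("calibration needs a single replicate per method", call. = FALSE)
  if (target_sd <= 0) stop("`target_sd` must be > 0", call. = FALSE)
  d <- sample$x[, 1] - sample$y[, 1]
  s0 <- stats::sd(d)
  if (s0 == 0)
    stop("observed differences have zero spread; cannot calibrate",
         call. = FALSE)
  d_new <- target_mean + (d - mean(d)) * (target_sd / s0)
  paired_sample(sample$y[, 1] + d_new, sample$y[, 1],
                subject_ids = sample$subject_ids,
                method_names = sample$method_names)
}
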