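#' Codon-position GC of a coding sequence
#'
#' Computes GC1, GC2, GC3 (the GC percentage at the first, second and
#' third codon position) and the overall GC of a CDS. A codon containing
#' any ambiguity code is skipped at all three positions, so the identity
#' `gc == (gc1 + gc2 + gc3) / 3` holds exactly. The terminal stop codon
#' is part of the CDS and included by default.
#'
#' @param cds Character scalar or [Biostrings::DNAString]; length must be
#'   a multiple of 3.
#' @param include_stop Include the final codon (default `TRUE`); when
#'   `FALSE` the last codon is dropped before counting.
#' @return Named numeric vector `c(gc, gc1, gc2, gc3, n_codons)` where
#'   `n_codons` is the number of unambiguous codons counted. GC values
#'   are `NA` when no codon could be counted.
#' @export
codon_gc <- function(cds, include_stop = TRUE) {
  if (!is.character(cds)) cds <- as.character(cds)
  stopifnot(length(cds) == 1L)
  s <- toupper(cds)
  len <- nchar(s)
  if (len %% 3L != 0L) {
    stop("CDS length (", len, ") is not a multiple of 3", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  m <- matrix(chars, nrow = 3L)  # row k = codon position k
  if (!include_stop && ncol(m) > 0L) m <- m[, -ncol(m), drop = FALSE]
  unambig <- matrix(m %in% c("A", "C", "G", "T"), nrow = 3L)
  keep <- colSums(unambig) == 3L
  n_cod <- sum(keep)
  if (n_cod == 0L) {
    return(c(gc = NA_real_, gc1 = NA_real_, gc2 = NA_real_,
             gc3 = NA_real_, n_codons = 0))
  }
  isgc <- matrix(m %in% c("G", "C"), nrow = 3L)[, keep, drop = FALSE]
  pos <- 100 * rowSums(isgc) / n_cod
  c(gc = mean(pos), gc1 = pos[1L], gc2 = pos[2L], gc3 = pos[3L],
    n_codons = n_cod)
}

#' Codon-position GC of a CDS set
#'
#' @param cds Named [Biostrings::DNAStringSet], named character vector,
#'   or a `clean_cds()` accepted data frame (columns `id`, `sequence`).
#' @param include_stop Passed to [codon_gc()].
#' @return Data frame with columns `id`, `gc`, `gc1`, `gc2`, `gc3`,
#'   `n_codons`.
#' @export
codon_gc_table <- function(cds, include_stop = TRUE) {
  if (is.data.frame(cds)) {
    ids <- cds$id; seqs <- cds$sequence
  } else {
    seqs <- as.character(cds)
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    ids <- sub("\\s.*$", "", ids)
  }
  vals <- t(vapply(seqs, codon_gc, numeric(5),
                   include_stop = include_stop, USE.NAMES = FALSE))
  data.frame(id = ids, gc = vals[, 1L], gc1 = vals[, 2L],
             gc2 = vals[, 3L], gc3 = vals[, 4L],
             n_codons = vals[, 5L], stringsAsFactors = FALSE)
}

#' Orthogonal (major-axis) regression
#'
#' Fits the line minimizing the summed squared perpendicular distances to
#' the points: the first principal axis of the 2x2 covariance matrix of
#' `(x, y)`. Appropriate when both variables are in the same units (here
#' % GC) and neither is an error-free predictor. The reported `r` is the
#' ordinary Pearson correlation. `method = "rma"` gives the reduced
#' major axis (slope `sign(cov) * sd(y)/sd(x)`) instead.
#'
#' @param x,y Equal-length numeric vectors (% GC); pairs with `NA` are
#'   dropped.
#' @param method `"ma"` (major axis, default) or `"rma"`.
#' @return Object of class `ma_fit`: list with `slope`, `intercept`, `r`,
#'   `n`, `method`.
#' @export
orthogonal_regression <- function(x, y, method = c("ma", "rma")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) {
    stop("zero variance: regression undefined", call. = FALSE)
  }
  if (method == "rma") {
    slope <- sign(sxy) * sqrt(syy / sxx)
    if (sxy == 0) slope <- sqrt(syy / sxx)
  } else if (sxy == 0) {
    # principal axis is parallel to the higher-variance coordinate
    if (sxx == syy) stop("major axis undefined: isotropic scatter",
                         call. = FALSE)
    slope <- if (sxx > syy) 0 else Inf
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  r <- if (sxx > 0 && syy > 0) stats::cor(x, y) else NA_real_
  structure(list(slope = slope, intercept = intercept, r = r, n = n,
                 method = method),
            class = "ma_fit")
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("%s regression: y = %.4f x %+.4f   R = %.4f   N = %d\n",
              if (x$method == "ma") "Major-axis" else "Reduced major-axis",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

# normalized histogram over fixed breaks; values outside [0,100] clipped
norm_hist <- function(v, bin_width) {
  v <- v[!is.na(v)]
  v <- pmin(pmax(v, 0), 100 - 1e-9)
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  counts <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1L],
             count = counts,
             fraction = if (length(v)) counts / length(v) else counts)
}

#' Histogram overlap of a statistic between two gene sets
#'
#' Shared area of the two normalized histograms: the sum over bins of the
#' minimum of the two bin fractions. 1 means identical histograms, 0
#' means disjoint supports.
#'
#' @param a,b Numeric vectors (% GC).
#' @param bin_width Histogram bin width in % (default 2.5).
#' @return Overlap fraction in `[0, 1]`.
#' @export
histogram_overlap <- function(a, b, bin_width = 2.5) {
  ha <- norm_hist(a, bin_width)
  hb <- norm_hist(b, bin_width)
  sum(pmin(ha$fraction, hb$fraction))
}

#' GC / GC1 / GC2 / GC3 distributions of two ortholog CDS sets
#'
#' Builds, on a shared axis, the per-species histograms of the four
#' statistics over an ortholog pairing, and reports per-statistic means
#' and between-species histogram overlaps; a shift of the distributions
#' with loss of overlap (especially in GC3) is the signature of
#' divergent compositional pressure between the two genomes.
#'
#' @param gc_a,gc_b Codon-GC tables from [codon_gc_table()] for species A
#'   and B, row-matched (one ortholog pair per row).
#' @param bin_width Histogram bin width in % (default 2.5).
#' @return List with `histograms` (data frame: species, statistic,
#'   bin_start, bin_end, count, fraction), `means` (data frame) and
#'   `overlap` (named numeric vector over gc, gc1, gc2, gc3).
#' @export
gc_distributions <- function(gc_a, gc_b, bin_width = 2.5) {
  stopifnot(nrow(gc_a) == nrow(gc_b), nrow(gc_a) >= 1L)
  stats_names <- c("gc", "gc1", "gc2", "gc3")
  hists <- list(); means <- list()
  overlap <- stats::setNames(numeric(4), stats_names)
  for (st in stats_names) {
    for (sp in c("a", "b")) {
      v <- if (sp == "a") gc_a[[st]] else gc_b[[st]]
      h <- norm_hist(v, bin_width)
      h$species <- sp; h$statistic <- st
      hists[[paste(st, sp)]] <- h
      means[[paste(st, sp)]] <- data.frame(
        species = sp, statistic = st, mean = mean(v, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
    overlap[st] <- histogram_overlap(gc_a[[st]], gc_b[[st]], bin_width)
  }
  list(histograms = do.call(rbind, c(hists, make.row.names = FALSE)),
       means = do.call(rbind, c(means, make.row.names = FALSE)),
       overlap = overlap)
}

#' All pairwise major-axis fits over codon-position statistics
#'
#' Within each species, fits every unordered pair of `gc`, `gc1`, `gc2`,
#' `gc3` against each other; between species, fits each statistic of
#' species B against the same statistic of species A. Fits that are
#' undefined (zero variance) are reported as rows of `NA`.
#'
#' @inheritParams gc_distributions
#' @param method Passed to [orthogonal_regression()].
#' @return Data frame with columns `scope` (`within_a`, `within_b`,
#'   `between`), `x_stat`, `y_stat`, `slope`, `intercept`, `r`, `n`.
#' @export
pairwise_position_fits <- function(gc_a, gc_b, method = "ma") {
  stopifnot(nrow(gc_a) == nrow(gc_b), nrow(gc_a) >= 3L)
  stats_names <- c("gc", "gc1", "gc2", "gc3")
  rows <- list()
  add_fit <- function(scope, xs, ys, x, y) {
    fit <- tryCatch(orthogonal_regression(x, y, method = method),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, x_stat = xs, y_stat = ys,
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      r = if (is.null(fit)) NA_real_ else fit$r,
      n = if (is.null(fit)) NA_integer_ else fit$n,
      stringsAsFactors = FALSE)
  }
  combos <- utils::combn(stats_names, 2L)
  for (k in seq_len(ncol(combos))) {
    xs <- combos[1L, k]; ys <- combos[2L, k]
    add_fit("within_a", xs, ys, gc_a[[xs]], gc_a[[ys]])
    add_fit("within_b", xs, ys, gc_b[[xs]], gc_b[[ys]])
  }
  for (st in stats_names) {
    add_fit("between", st, st, gc_a[[st]], gc_b[[st]])
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Scatterplot of one major-axis fit
#'
#' @param x,y Numeric vectors.
#' @param fit An `ma_fit` for the same data (computed if `NULL`).
#' @param xlab,ylab Axis labels.
#' @export
plot_fit <- function(x, y, fit = NULL, xlab = "x (% GC)",
                     ylab = "y (% GC)") {
  if (is.null(fit)) fit <- orthogonal_regression(x, y)
  graphics::plot(x, y, pch = 20, cex = 0.4, xlab = xlab, ylab = ylab,
                 main = sprintf("y = %.2f x %+.2f  R = %.2f  N = %d",
                                fit$slope, fit$intercept, fit$r, fit$n))
  graphics::abline(0, 1, lty = 2)
  if (is.finite(fit$slope)) graphics::abline(fit$intercept, fit$slope)
  invisible(fit)
}
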