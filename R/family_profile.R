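#' Pool segments into GC bins ("distribution by weight")
#'
#' Each segment contributes its full length, in bases, to the bin
#' containing its GC level. Bins are left-closed right-open intervals
#' `[x, x + bin_width)` anchored at 0% GC, so a segment at exactly 40.5%
#' falls in the `[40.5, 41)` bin.
#'
#' @param segments Segment data frame with `gc_percent` and `size`
#'   columns (from [segment_chromosome()] / [segment_genome()]).
#' @param bin_width Bin width in % GC (default 0.5).
#' @return A data frame of class `binned_profile` with columns
#'   `bin_start`, `bin_end`, `weight_bp`, `weight_mb`, `weight_fraction`,
#'   covering the occupied bin range contiguously (zero-weight bins
#'   included). The bin width is stored as attribute `bin_width`.
#' @export
bin_segments <- function(segments, bin_width = 0.5) {
  if (is.null(segments) || nrow(segments) == 0L) {
    stop("cannot bin an empty segment set", call. = FALSE)
  }
  stopifnot(bin_width > 0)
  idx <- floor(segments$gc_percent / bin_width)
  lo <- min(idx); hi <- max(idx)
  w <- numeric(hi - lo + 1L)
  tal <- tapply(segments$size, idx, sum)
  w[as.integer(names(tal)) - lo + 1L] <- as.numeric(tal)
  total <- sum(w)
  prof <- data.frame(
    bin_start = (lo:hi) * bin_width,
    bin_end = (lo:hi + 1) * bin_width,
    weight_bp = w,
    weight_mb = w / 1e6,
    weight_fraction = if (total > 0) w / total else w
  )
  structure(prof, class = c("binned_profile", "data.frame"),
            bin_width = bin_width)
}

#' Default family class boundaries
#'
#' GC cutpoints separating the L1/L2/H1/H2/H3 isochore families, chosen
#' to bracket the canonical vertebrate family averages
#' (36.2/39.1/43.3/48.3/54.8% GC), plus outer bounds beyond which a
#' family is called compositionally extreme rather than assigned to the
#' vertebrate scheme.
#'
#' @param l1_l2,l2_h1,h1_h2,h2_h3 Cutpoints in % GC (left-closed
#'   intervals).
#' @param extreme_low_below Families with mean GC below this are labelled
#'   `extreme-low`.
#' @param extreme_high_above Families with mean GC at or above this are
#'   labelled `extreme-high`.
#' @return A list of class `family_boundaries`.
#' @export
family_boundaries <- function(l1_l2 = 37, l2_h1 = 41, h1_h2 = 46,
                              h2_h3 = 53, extreme_low_below = 30,
                              extreme_high_above = 57.5) {
  cuts <- c(l1_l2, l2_h1, h1_h2, h2_h3)
  stopifnot(all(diff(cuts) > 0),
            extreme_low_below < l1_l2,
            extreme_high_above > h2_h3)
  structure(list(l1_l2 = l1_l2, l2_h1 = l2_h1, h1_h2 = h1_h2,
                 h2_h3 = h2_h3, extreme_low_below = extreme_low_below,
                 extreme_high_above = extreme_high_above),
            class = "family_boundaries")
}

#' Classify a family mean GC against the isochore scheme
#'
#' Exhaustive and exclusive: every real mean GC receives exactly one of
#' `extreme-low`, `L1`, `L2`, `H1`, `H2`, `H3`, `extreme-high`. All
#' intervals are left-closed.
#'
#' @param mean_gc Numeric vector of family mean GC levels (%).
#' @param boundaries A [family_boundaries()] object.
#' @return Character vector of labels.
#' @export
classify_family <- function(mean_gc, boundaries = family_boundaries()) {
  b <- boundaries
  cuts <- c(-Inf, b$extreme_low_below, b$l1_l2, b$l2_h1, b$h1_h2,
            b$h2_h3, b$extreme_high_above, Inf)
  labs <- c("extreme-low", "L1", "L2", "H1", "H2", "H3", "extreme-high")
  labs[findInterval(mean_gc, cuts, left.open = FALSE)]
}

#' Detect compositional families in a binned profile
#'
#' A reproducible surrogate for reading families off a binned histogram:
#' the profile is smoothed by a centered moving average over
#' `smooth_bins` bins (zero weight assumed outside the occupied range);
#' local maxima of the smoothed profile are candidate family modes;
#' family boundaries are placed at the (first) local minimum between
#' consecutive modes, the valley bin joining the left family; candidates
#' carrying less than `min_family_fraction` of the total weight are
#' merged into the heavier of their flanking families until none remain.
#' Family weight, mean and span are computed from the raw (unsmoothed)
#' weights of member bins.
#'
#' @param profile A `binned_profile` from [bin_segments()].
#' @param min_family_fraction Minimum weight fraction for a family to
#'   stand on its own (default 0.02).
#' @param smooth_bins Odd width of the moving-average smoother in bins
#'   (default 3).
#' @param segments Optional segment data frame; when supplied, family
#'   mean GC is the length-weighted mean of the raw GC of member
#'   segments instead of the weighted mean of bin midpoints.
#' @return Data frame of class `family_set`, one row per family ordered
#'   by mean GC: `mean_gc`, `relative_amount` (% of total weight),
#'   `gc_min`, `gc_max` (span of occupied member-bin midpoints),
#'   `weight_bp`, `label` (from [classify_family()] with default
#'   boundaries; reclassify with other boundaries if needed).
#' @export
detect_families <- function(profile, min_family_fraction = 0.02,
                            smooth_bins = 3L, segments = NULL) {
  stopifnot(inherits(profile, "binned_profile"))
  smooth_bins <- as.integer(smooth_bins)
  stopifnot(smooth_bins >= 1L, smooth_bins %% 2L == 1L,
            min_family_fraction >= 0, min_family_fraction < 1)
  w <- profile$weight_bp
  total <- sum(w)
  if (total <= 0) stop("profile has zero total weight", call. = FALSE)
  n <- length(w)
  bw <- attr(profile, "bin_width")
  mids <- profile$bin_start + bw / 2

  # centered moving average, zero-padded beyond the occupied range
  h <- (smooth_bins - 1L) %/% 2L
  padded <- c(numeric(h), w, numeric(h))
  sm <- vapply(seq_len(n), function(i) {
    mean(padded[i:(i + 2L * h)])
  }, 0)

  # local maxima of the smoothed profile; plateaus count once, at their
  # central bin (zero assumed outside the range)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sm[j + 1L] == sm[i]) j <- j + 1L
    left <- if (i == 1L) 0 else sm[i - 1L]
    right <- if (j == n) 0 else sm[j + 1L]
    if (sm[i] > 0 && sm[i] >= left && sm[i] >= right) {
      peaks <- c(peaks, (i + j) %/% 2L)
    }
    i <- j + 1L
  }
  if (!length(peaks)) peaks <- which.max(sm)

  # boundaries at valleys between consecutive peaks; valley joins left
  assign <- rep.int(1L, n)
  if (length(peaks) > 1L) {
    cuts <- vapply(seq_len(length(peaks) - 1L), function(k) {
      rng <- seq.int(peaks[k] + 1L, peaks[k + 1L] - 1L)
      if (!length(rng)) return(peaks[k])
      rng[which.min(sm[rng])]
    }, 0L)
    assign <- findInterval(seq_len(n), cuts + 0.5) + 1L
  }

  fam_weight <- function(a) as.numeric(tapply(w, a, sum))
  wt <- fam_weight(assign)
  # merge under-weight candidates into the heavier flanking family
  while (length(wt) > 1L && any(wt / total < min_family_fraction)) {
    small <- which.min(wt)
    nb <- c(small - 1L, small + 1L)
    nb <- nb[nb >= 1L & nb <= length(wt)]
    target <- nb[which.max(wt[nb])]
    assign[assign == small] <- target
    assign <- match(assign, sort(unique(assign)))
    wt <- fam_weight(assign)
  }

  k <- length(wt)
  mean_gc <- numeric(k); gc_min <- numeric(k); gc_max <- numeric(k)
  for (f in seq_len(k)) {
    member <- assign == f
    occ <- member & w > 0
    mean_gc[f] <- sum(w[member] * mids[member]) / wt[f]
    if (!is.null(segments)) {
      sidx <- floor(segments$gc_percent / bw) * bw
      infam <- sidx >= min(profile$bin_start[member]) &
        sidx <= max(profile$bin_start[member])
      if (any(infam)) {
        mean_gc[f] <- sum(segments$size[infam] *
                            segments$gc_percent[infam]) /
          sum(segments$size[infam])
      }
    }
    gc_min[f] <- if (any(occ)) min(mids[occ]) else NA_real_
    gc_max[f] <- if (any(occ)) max(mids[occ]) else NA_real_
  }
  ord <- order(mean_gc)
  out <- data.frame(
    mean_gc = mean_gc[ord],
    relative_amount = 100 * wt[ord] / total,
    gc_min = gc_min[ord],
    gc_max = gc_max[ord],
    weight_bp = wt[ord],
    label = classify_family(mean_gc[ord]),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("family_set", "data.frame"))
}

#' Tabular family report
#'
#' One row per family with mean GC and relative amount rounded to one
#' decimal; amounts rounding to 99.5% or more are reported as `"~100"`,
#' the convention for genomes consisting of a single family.
#'
#' @param families A `family_set` from [detect_families()] (may have zero
#'   rows).
#' @param species Species name repeated on each row.
#' @param boundaries A [family_boundaries()] object used to (re)label.
#' @return Data frame with columns `species`, `label`, `mean_gc`,
#'   `relative_amount` (character, to carry the `~100` annotation).
#' @export
family_table <- function(families, species = "",
                         boundaries = family_boundaries()) {
  if (is.null(families) || nrow(families) == 0L) {
    return(data.frame(species = character(), label = character(),
                      mean_gc = numeric(), relative_amount = character(),
                      stringsAsFactors = FALSE))
  }
  amt <- vapply(families$relative_amount, function(a) {
    if (a >= 99.5) "~100" else sprintf("%.1f", a)
  }, "")
  data.frame(
    species = species,
    label = classify_family(families$mean_gc, boundaries),
    mean_gc = round(families$mean_gc, 1),
    relative_amount = amt,
    stringsAsFactors = FALSE
  )
}

#' Write a binned profile as TSV
#'
#' @param profile A `binned_profile`.
#' @param path Output path.
#' @export
write_profile_table <- function(profile, path) {
  write.table(
    profile[, c("bin_start", "bin_end", "weight_mb", "weight_fraction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a distribution of DNA by weight
#'
#' Histogram-style barplot of megabases of DNA per GC bin, the standard
#' way compositional profiles are displayed.
#'
#' @param profile A `binned_profile`.
#' @param main Plot title.
#' @export
plot_profile <- function(profile, main = "DNA distribution by weight") {
  graphics::barplot(profile$weight_mb,
                    names.arg = sprintf("%.1f", profile$bin_start),
                    space = 0, las = 2, cex.names = 0.6,
                    xlab = "GC (%)", ylab = "DNA (Mb)", main = main)
  invisible(profile)
}
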