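#' Segmentation parameters
#'
#' Bundle of the three tunables of the window/segment stage.
#'
#' @param window_size Non-overlapping window size in bases. 25 kb is small
#'   enough to resolve the short chromosomes of unicellular genomes while
#'   keeping window GC estimates tight (binomial s.e. ~0.3% GC at 50% GC).
#' @param merge_threshold Maximum allowed absolute difference, in % GC,
#'   between a window and the running mean of the segment it would join.
#' @param min_valid_fraction Minimum fraction of unambiguous (A/C/G/T)
#'   bases for a window to be used; gap-rich windows are flagged invalid
#'   and break segments rather than bridging them.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(window_size = 25000L,
                                merge_threshold = 1.5,
                                min_valid_fraction = 0.5) {
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 1000L, merge_threshold > 0,
            min_valid_fraction >= 0, min_valid_fraction <= 1)
  structure(list(window_size = window_size,
                 merge_threshold = merge_threshold,
                 min_valid_fraction = min_valid_fraction),
            class = "segmentation_params")
}

#' Partition one sequence into fixed non-overlapping GC windows
#'
#' The sequence is cut into `floor(length / window_size)` windows of
#' exactly `window_size` bases; a trailing remainder shorter than one
#' window is discarded so all windows are equal-length and segment GC is
#' an unweighted mean of window GC values. Window GC excludes ambiguity
#' codes from numerator and denominator; windows with fewer than
#' `min_valid_fraction * window_size` unambiguous bases are flagged
#' invalid.
#'
#' @param record A [Biostrings::DNAString], single-element
#'   [Biostrings::DNAStringSet], or character scalar.
#' @param params A [segmentation_params()] object.
#' @param chrom_id Identifier stored in the `chrom` column.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc_percent`, `valid`. Zero rows (with a warning) when
#'   the record is shorter than one window.
#' @export
partition_windows <- function(record, params = segmentation_params(),
                              chrom_id = "chr") {
  if (is.character(record)) record <- Biostrings::DNAString(record)
  if (inherits(record, "DNAStringSet")) {
    stopifnot(length(record) == 1L)
    if (!is.null(names(record))) chrom_id <- names(record)[1L]
    record <- record[[1L]]
  }
  ws <- params$window_size
  len <- length(record)
  n <- len %/% ws
  if (n == 0L) {
    warning("record '", chrom_id, "' (", len,
            " bases) is shorter than one window; no windows produced")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gc_percent = numeric(),
                      valid = logical()))
  }
  views <- IRanges::successiveViews(record, rep.int(ws, n))
  f <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"), OR = 0)
  unambig <- rowSums(f)
  gc <- ifelse(unambig > 0, 100 * (f[, "G"] + f[, "C"]) / unambig, NA_real_)
  data.frame(
    chrom = chrom_id,
    start = (seq_len(n) - 1L) * ws,
    end = seq_len(n) * ws,
    gc_percent = gc,
    valid = unambig / ws >= params$min_valid_fraction,
    stringsAsFactors = FALSE
  )
}

#' Merge windows into compositionally homogeneous segments
#'
#' Greedy left-to-right merging: the first valid window opens a segment;
#' each subsequent valid window joins the open segment if and only if the
#' absolute difference between its GC and the running (unweighted) mean GC
#' of the segment's member windows is at most `merge_threshold`; otherwise
#' it opens a new segment. Invalid windows close the open segment, so
#' segments never span assembly gaps.
#'
#' @param windows Window data frame from [partition_windows()], one
#'   chromosome, ordered by `start`.
#' @param params A [segmentation_params()] object.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `size`, `gc_percent` (mean GC of member windows).
#' @export
segment_chromosome <- function(windows, params = segmentation_params()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      size = numeric(), gc_percent = numeric())
  if (nrow(windows) == 0L) return(empty)
  stopifnot(!is.unsorted(windows$start))
  thr <- params$merge_threshold

  segs <- list()
  cur <- NULL  # list(start, end, sum_gc, n)
  close_cur <- function() {
    if (!is.null(cur)) segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_len(nrow(windows))) {
    if (!isTRUE(windows$valid[i]) || is.na(windows$gc_percent[i])) {
      close_cur()
      next
    }
    g <- windows$gc_percent[i]
    s <- windows$start[i]; e <- windows$end[i]
    if (!is.null(cur) &&
        s == cur$end &&
        abs(g - cur$sum_gc / cur$n) <= thr) {
      cur$end <- e
      cur$sum_gc <- cur$sum_gc + g
      cur$n <- cur$n + 1L
    } else {
      close_cur()
      cur <- list(start = s, end = e, sum_gc = g, n = 1L)
    }
  }
  close_cur()
  if (!length(segs)) return(empty)
  data.frame(
    chrom = windows$chrom[1L],
    start = vapply(segs, `[[`, 0, "start"),
    end = vapply(segs, `[[`, 0, "end"),
    n_windows = vapply(segs, function(x) as.integer(x$n), 0L),
    size = vapply(segs, function(x) as.numeric(x$end - x$start), 0),
    gc_percent = vapply(segs, function(x) x$sum_gc / x$n, 0),
    stringsAsFactors = FALSE
  )
}

#' Conventional segment name
#'
#' The name concatenates the chromosome number, the initials of the
#' scientific name (genus upper-case, species lower-case) and the running
#' segment index on that chromosome, e.g. `"3Sc2"` for the second segment
#' of *Saccharomyces cerevisiae* chromosome 3. No separators are used.
#'
#' @param chromosome_number Positive integer.
#' @param species_name Binomial name; must contain at least genus and
#'   species words.
#' @param index Positive integer, segment rank on the chromosome.
#' @return Character scalar.
#' @export
name_segment <- function(chromosome_number, species_name, index) {
  stopifnot(chromosome_number >= 1, index >= 1)
  words <- strsplit(trimws(species_name), "\\s+")[[1L]]
  if (length(words) < 2L) {
    stop("species_name must contain at least genus and species: '",
         species_name, "'", call. = FALSE)
  }
  paste0(chromosome_number,
         toupper(substr(words[1L], 1L, 1L)),
         tolower(substr(words[2L], 1L, 1L)),
         index)
}

#' Segment every record of an assembly
#'
#' Runs [partition_windows()] and [segment_chromosome()] per record and,
#' when a species name is given, names segments by the conventional
#' scheme. Chromosome numbers default to record order.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param params A [segmentation_params()] object.
#' @param species Optional binomial species name used for segment names.
#' @param chromosome_numbers Optional named integer vector mapping record
#'   names to chromosome numbers; defaults to record order.
#' @return A list with `windows` and `segments` data frames (all records
#'   concatenated).
#' @export
segment_genome <- function(assembly, params = segmentation_params(),
                           species = NULL, chromosome_numbers = NULL) {
  stopifnot(length(assembly) > 0L)
  ids <- names(assembly)
  if (is.null(ids)) ids <- as.character(seq_along(assembly))
  if (is.null(chromosome_numbers)) {
    chromosome_numbers <- stats::setNames(seq_along(assembly), ids)
  }
  win_list <- vector("list", length(assembly))
  seg_list <- vector("list", length(assembly))
  for (i in seq_along(assembly)) {
    w <- partition_windows(assembly[[i]], params, chrom_id = ids[i])
    s <- segment_chromosome(w, params)
    if (nrow(s) && !is.null(species)) {
      s$name <- vapply(seq_len(nrow(s)), function(k) {
        name_segment(chromosome_numbers[[ids[i]]], species, k)
      }, "")
    }
    win_list[[i]] <- w
    seg_list[[i]] <- s
  }
  list(windows = do.call(rbind, win_list),
       segments = do.call(rbind, seg_list))
}

#' Compositional heterogeneity of a window set
#'
#' Sample standard deviation of the GC levels of valid windows; the
#' standard measure of how compartmentalized a genome looks at a given
#' window size (it tends to decrease as the window grows).
#'
#' @param windows Window data frame from [partition_windows()] (one or
#'   several chromosomes).
#' @return Standard deviation in % GC.
#' @export
heterogeneity <- function(windows) {
  g <- windows$gc_percent[windows$valid & !is.na(windows$gc_percent)]
  if (length(g) < 2L) {
    stop("heterogeneity needs at least 2 valid windows", call. = FALSE)
  }
  stats::sd(g)
}

#' Run the window/segment/bin pipeline at several window sizes
#'
#' Used to check that a compositional pattern is not an artifact of the
#' window size: the same record is profiled at each size with otherwise
#' identical parameters.
#'
#' @param record Sequence as accepted by [partition_windows()].
#' @param sizes Integer vector of window sizes in bases.
#' @param params Base [segmentation_params()]; `window_size` is replaced
#'   per run.
#' @param bin_width Bin width in % GC for the pooled profile.
#' @return Named list (one element per size) of lists with `windows`,
#'   `segments`, `profile` and `heterogeneity`.
#' @export
compare_window_sizes <- function(record, sizes = c(25000L, 100000L),
                                 params = segmentation_params(),
                                 bin_width = 0.5) {
  res <- lapply(sizes, function(ws) {
    p <- segmentation_params(window_size = ws,
                             merge_threshold = params$merge_threshold,
                             min_valid_fraction = params$min_valid_fraction)
    w <- partition_windows(record, p)
    s <- segment_chromosome(w, p)
    list(windows = w, segments = s,
         profile = bin_segments(s, bin_width = bin_width),
         heterogeneity = heterogeneity(w))
  })
  names(res) <- as.character(as.integer(sizes))
  res
}
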