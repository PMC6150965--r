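#' Construct a fluorescence histogram
#'
#' Binned flow-cytometry event counts on a strictly increasing channel
#' axis (arbitrary fluorescence units).
#'
#' @param channel_values ordered numeric bin centers.
#' @param counts non-negative event counts per bin.
#' @return object of class `fluorescence_histogram`.
#' @export
fluorescence_histogram <- function(channel_values, counts) {
  channel_values <- as.numeric(channel_values)
  counts <- as.numeric(counts)
  if (length(channel_values) != length(counts))
    stop_domain("channels and counts must have equal length")
  if (is.unsorted(channel_values, strictly = TRUE))
    stop_domain("channel values must be strictly increasing")
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  structure(list(channel_values = channel_values, counts = counts,
                 total_events = sum(counts)),
            class = "fluorescence_histogram")
}

#' @export
print.fluorescence_histogram <- function(x, ...) {
  cat(sprintf("<fluorescence_histogram> %d bins, %s events, channels [%g, %g]\n",
              length(x$counts), format(x$total_events, big.mark = ","),
              min(x$channel_values), max(x$channel_values)))
  invisible(x)
}

#' Read / write a histogram CSV (channel,count)
#'
#' @param path file path to a two-column CSV with header `channel,count`.
#' @return a [fluorescence_histogram()].
#' @export
read_histogram <- function(path) {
  x <- read.csv(path)
  if (!all(c("channel", "count") %in% names(x)))
    stop_domain("histogram CSV must have columns channel, count")
  fluorescence_histogram(x$channel, x$count)
}

#' @rdname read_histogram
#' @param hist a `fluorescence_histogram`.
#' @export
write_histogram <- function(hist, path) {
  write.csv(data.frame(channel = hist$channel_values, count = hist$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect fluorescence peaks in a histogram
#'
#' Finds local count maxima separated by at least the window halfwidth and
#' keeps those whose windowed event count reaches `min_fraction` of the
#' total.  Each retained peak is summarized by the event-weighted mean and
#' sample SD of the channel values within +/- `window_halfwidth` of the
#' apex, and peaks are returned in ascending order of mean channel.
#'
#' @param hist a [fluorescence_histogram()].
#' @param min_fraction minimum fraction of total events a peak window must
#'   contain (default 0.05).
#' @param window_halfwidth half-width of the summarization window, in
#'   channel units (default 30; comfortably wider than a few SD of a
#'   low-CV G0/G1 peak on a 1024-channel axis).
#' @return data.frame of class `peak_estimates` with columns
#'   `mean_channel`, `sd_channel`, `cv`, `event_count`; zero rows when no
#'   qualifying peak exists.
#' @export
find_peaks <- function(hist, min_fraction = 0.05, window_halfwidth = 30) {
  stopifnot(inherits(hist, "fluorescence_histogram"))
  ch <- hist$channel_values; n <- hist$counts
  if (!length(ch) || hist$total_events == 0) return(empty_peaks())

  # apex candidates: strictly the maximum count within the local window
  cand <- integer()
  for (i in seq_along(ch)) {
    if (n[i] == 0) next
    win <- which(abs(ch - ch[i]) <= window_halfwidth)
    if (n[i] == max(n[win]) && i == min(win[n[win] == n[i]]))
      cand <- c(cand, i)
  }
  if (!length(cand)) return(empty_peaks())

  peaks <- lapply(cand, function(i) {
    win <- which(abs(ch - ch[i]) <= window_halfwidth)
    ev <- sum(n[win])
    if (ev < min_fraction * hist$total_events) return(NULL)
    m <- weighted.mean(ch[win], n[win])
    v <- sum(n[win] * (ch[win] - m)^2) / max(ev - 1, 1)
    data.frame(mean_channel = m, sd_channel = sqrt(v),
               cv = sqrt(v) / m, event_count = ev)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks) || !nrow(peaks)) return(empty_peaks())
  peaks <- peaks[order(peaks$mean_channel), , drop = FALSE]
  # merge duplicates pointing at the same mode
  keep <- c(TRUE, diff(peaks$mean_channel) > window_halfwidth / 2)
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_estimates", "data.frame")
  peaks
}

empty_peaks <- function() {
  structure(data.frame(mean_channel = numeric(), sd_channel = numeric(),
                       cv = numeric(), event_count = numeric()),
            class = c("peak_estimates", "data.frame"))
}

#' Estimate the 1C genome size from peak positions
#'
#' Internal-standard ratio method: the unknown's DNA content is the ratio
#' of its peak fluorescence to the standard's peak fluorescence times the
#' standard's known 1C value (both taken from the same-ploidy nuclei
#' population, so the ratio cancels instrument gain).
#'
#' @param sample_peak,standard_peak one-row peak estimates (or anything
#'   with a `mean_channel` field) for the unknown and the internal
#'   standard.
#' @param standard_1c_pg known 1C value of the standard in pg (default
#'   0.18, Drosophila melanogaster).
#' @return 1C value of the sample in pg.
#' @export
estimate_1c <- function(sample_peak, standard_peak, standard_1c_pg = 0.18) {
  ms <- sample_peak$mean_channel[1]
  mr <- standard_peak$mean_channel[1]
  if (!is.finite(mr) || mr <= 0) stop_domain("standard peak mean must be > 0")
  if (!is.finite(ms) || ms <= 0) stop_domain("sample peak mean must be > 0")
  ms / mr * standard_1c_pg
}

#' Convert picograms of DNA to megabase pairs
#'
#' Uses the standard equivalence 1 pg = 978 Mbp.
#'
#' @param pg DNA mass in pg, >= 0.
#' @return length in Mbp.
#' @examples
#' pg_to_mbp(0.35)  # 342.3
#' @export
pg_to_mbp <- function(pg) {
  if (any(pg < 0)) stop_domain("mass must be >= 0")
  pg * 978
}

#' @rdname pg_to_mbp
#' @param mbp length in Mbp, >= 0.
#' @export
mbp_to_pg <- function(mbp) {
  if (any(mbp < 0)) stop_domain("length must be >= 0")
  mbp / 978
}

#' Quality-control a histogram and its peaks
#'
#' A run fails QC when any peak used for estimation has a coefficient of
#' variation above `cv_max` (default 5%) or when fewer than `min_nuclei`
#' events were acquired (default 10,000).
#'
#' @param hist a [fluorescence_histogram()].
#' @param peaks peak estimates from [find_peaks()] (the peaks actually
#'   used, typically sample + standard).
#' @param cv_max maximum allowed peak CV.
#' @param min_nuclei minimum total event count.
#' @return list with `pass` (logical) and `reasons` (character vector,
#'   subset of `"cv"`, `"nuclei"`, `"no_peaks"`).
#' @export
qc_histogram <- function(hist, peaks, cv_max = 0.05, min_nuclei = 10000) {
  reasons <- character()
  if (is.null(peaks) || !nrow(peaks)) reasons <- c(reasons, "no_peaks")
  else if (any(peaks$cv > cv_max)) reasons <- c(reasons, "cv")
  if (hist$total_events < min_nuclei) reasons <- c(reasons, "nuclei")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Genome-size estimate for one histogram
#'
#' End-to-end single-replicate estimation: detect peaks, identify the
#' internal-standard peak, QC, and convert the peak ratio into 1C/2C pg
#' and Mbp.  The standard peak is the one nearest `expected_standard_channel`
#' when given; otherwise the lowest-fluorescence qualifying peak is taken
#' as the standard (appropriate when the sample genome exceeds the
#' standard's, as for an ant sample against Drosophila).
#'
#' @inheritParams find_peaks
#' @inheritParams qc_histogram
#' @param standard_1c_pg 1C value of the internal standard (pg).
#' @param expected_standard_channel approximate channel of the standard
#'   peak, or `NULL` (default) to use the lowest peak.
#' @return object of class `genome_size_estimate`: list with `c1_pg`,
#'   `c2_pg`, `mbp`, `standard_1c_pg`, `qc_pass`, `qc_reasons`,
#'   `sample_peak`, `standard_peak`.
#' @export
estimate_genome_size <- function(hist, standard_1c_pg = 0.18,
                                 expected_standard_channel = NULL,
                                 min_fraction = 0.05, window_halfwidth = 30,
                                 cv_max = 0.05, min_nuclei = 10000) {
  peaks <- find_peaks(hist, min_fraction, window_halfwidth)
  if (nrow(peaks) < 2) {
    qc <- qc_histogram(hist, peaks, cv_max, min_nuclei)
    return(structure(list(c1_pg = NA_real_, c2_pg = NA_real_,
                          mbp = NA_real_, standard_1c_pg = standard_1c_pg,
                          qc_pass = FALSE,
                          qc_reasons = unique(c(qc$reasons, "no_peaks")),
                          sample_peak = NULL, standard_peak = NULL),
                     class = "genome_size_estimate"))
  }
  std_idx <- if (is.null(expected_standard_channel)) 1L
  else which.min(abs(peaks$mean_channel - expected_standard_channel))
  smp_idx <- setdiff(order(-peaks$event_count), std_idx)[1]
  standard_peak <- peaks[std_idx, ]; sample_peak <- peaks[smp_idx, ]
  qc <- qc_histogram(hist, rbind(standard_peak, sample_peak),
                     cv_max, min_nuclei)
  c1 <- estimate_1c(sample_peak, standard_peak, standard_1c_pg)
  structure(list(c1_pg = c1, c2_pg = 2 * c1, mbp = pg_to_mbp(c1),
                 standard_1c_pg = standard_1c_pg, qc_pass = qc$pass,
                 qc_reasons = qc$reasons, sample_peak = sample_peak,
                 standard_peak = standard_peak),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("1C = %.3f pg (%.1f Mbp), 2C = %.3f pg  [QC %s%s]\n",
              x$c1_pg, x$mbp, x$c2_pg,
              if (x$qc_pass) "pass" else "FAIL",
              if (length(x$qc_reasons))
                paste0(": ", paste(x$qc_reasons, collapse = ", ")) else ""))
  invisible(x)
}

#' Aggregate replicate genome-size estimates
#'
#' Pools QC-passing replicates of one population into a population-level
#' estimate: mean and sample SD of the replicate 1C values, with 2C and
#' Mbp recomputed from the mean.
#'
#' @param estimates list of `genome_size_estimate` objects.
#' @param min_replicates minimum number of QC-passing replicates required
#'   (default 3).
#' @return list of class `genome_size_estimate` with additional fields
#'   `replicate_mean_pg`, `replicate_sd_pg`, `n_replicates`.
#' @export
aggregate_replicates <- function(estimates, min_replicates = 3) {
  passing <- Filter(function(e) isTRUE(e$qc_pass), estimates)
  if (length(passing) < min_replicates)
    stop_domain("only ", length(passing), " QC-passing replicate(s); ",
                "need >= ", min_replicates)
  c1 <- vapply(passing, `[[`, 0, "c1_pg")
  m <- mean(c1)
  structure(list(c1_pg = m, c2_pg = 2 * m, mbp = pg_to_mbp(m),
                 standard_1c_pg = passing[[1]]$standard_1c_pg,
                 replicate_mean_pg = m,
                 replicate_sd_pg = if (length(c1) >= 2) sd(c1) else 0,
                 n_replicates = length(c1), qc_pass = TRUE,
                 qc_reasons = character()),
            class = "genome_size_estimate")
}
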