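# K-mer over-representation analysis of CLIP tags against a matched
# random-genomic control: overlapping-window k-mer counting with N-window
# exclusion, per-k-mer 2x2 chi-squared tests, top-motif selection and
# sequence-logo count matrices.
#
# The counting unit is the window: a tag of length L contributes
# max(0, L - k + 1) overlapping windows, minus any window containing N.
# Each k-mer's 2x2 table is then
#   [[occurrence windows, other windows]  (CLIP)
#    [occurrence windows, other windows]] (control).

#' Count overlapping k-mers in a tag set
#'
#' Windows containing \code{N} are skipped and excluded from
#' \code{total_windows}.  K-mers never observed have implicit count 0
#' (query with \code{\link{kmer_count}}).
#'
#' @param tags a \code{tag_set} (RNA alphabet).
#' @param k window length (>= 1), default 6.
#' @return An object of class \code{kmer_table}: list with \code{k},
#'   \code{counts} (named integer vector over observed k-mers) and
#'   \code{total_windows}.
#' @examples
#' count_kmers(tag_set("AAAA"), k = 3)  # AAA counted twice
#' @export
count_kmers <- function(tags, k = 6L) {
  stopifnot(inherits(tags, "tag_set"), k >= 1)
  k <- as.integer(k)
  lens <- nchar(tags$seq)
  usable <- which(lens >= k)
  if (length(tags) > 0L && length(usable) == 0L)
    warning(sprintf("k = %d exceeds every sequence length; no windows", k))
  windows <- character(0)
  if (length(usable)) {
    windows <- unlist(lapply(tags$seq[usable], function(s) {
      n <- nchar(s)
      starts <- seq_len(n - k + 1L)
      substring(s, starts, starts + k - 1L)
    }), use.names = FALSE)
    windows <- windows[!grepl("N", windows, fixed = TRUE)]
  }
  counts <- if (length(windows)) {
    tb <- table(windows)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  structure(list(k = k, counts = counts,
                 total_windows = length(windows)),
            class = "kmer_table")
}

#' Look up a k-mer count (0 when absent)
#' @param table a \code{kmer_table}.
#' @param kmer character vector of k-mers.
#' @return Integer counts.
#' @export
kmer_count <- function(table, kmer) {
  stopifnot(inherits(table, "kmer_table"))
  out <- table$counts[kmer]
  out[is.na(out)] <- 0L
  stats::setNames(as.integer(out), kmer)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, %d distinct k-mers, %d windows\n",
              x$k, length(x$counts), x$total_windows))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 occurrence table
#'
#' Computes the 1-df Pearson statistic, without continuity correction, on
#' \code{[[obs_count, obs_total - obs_count], [bg_count, bg_total -
#' bg_count]]} via the closed form
#' \code{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, and its upper-tail
#' p-value.  A zero marginal (k-mer absent from, or saturating, both sets)
#' yields \code{chi2 = 0, p = 1} with \code{degenerate = TRUE}.
#'
#' All arguments are vectorized.
#'
#' @param obs_count,obs_total occurrence and total windows in the CLIP set.
#' @param bg_count,bg_total occurrence and total windows in the control.
#' @return A data frame with columns \code{chi2}, \code{p_value},
#'   \code{degenerate}.
#' @examples
#' chi2_two_by_two(30, 100, 10, 100)  # chi2 = 12.5
#' @export
chi2_two_by_two <- function(obs_count, obs_total, bg_count, bg_total) {
  stopifnot(all(obs_total > 0), all(bg_total > 0),
            all(obs_count >= 0), all(bg_count >= 0),
            all(obs_count <= obs_total), all(bg_count <= bg_total))
  a <- as.numeric(obs_count); b <- as.numeric(obs_total) - a
  c_ <- as.numeric(bg_count); d <- as.numeric(bg_total) - c_
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom == 0, 0, n * (a * d - b * c_)^2 / denom)
  p <- ifelse(denom == 0, 1, stats::pchisq(chi2, df = 1,
                                           lower.tail = FALSE))
  data.frame(chi2 = chi2, p_value = p, degenerate = denom == 0)
}

#' Score k-mer over-representation in CLIP tags versus a control
#'
#' One result row per k-mer observed in either set, carrying observed and
#' background window counts, the enrichment ratio, the chi-squared
#' statistic and its p-value.  The ratio is
#' \code{(obs_count/obs_total) / (bg_count/bg_total)}; when any cell of
#' the 2x2 table is zero, 0.5 is added to all four cells for the ratio
#' only (chi2 and p are always computed on raw counts).  Rows are ordered
#' by rank: descending ratio, ties by ascending p, then k-mer.
#'
#' The \code{significant} column marks \code{p < alpha} and
#' \code{ratio > 1}; with \code{correction = "bonferroni"} the threshold
#' is applied to \code{p * 4^k} instead (off by default).
#'
#' @param clip,control non-empty \code{tag_set}s.
#' @param k k-mer length, default 6.
#' @param alpha significance level for the filtered view, default 0.05.
#' @param correction \code{"none"} (default) or \code{"bonferroni"}.
#' @return A data frame of class \code{kmer_enrichment} with columns
#'   \code{kmer}, \code{obs_count}, \code{obs_total}, \code{bg_count},
#'   \code{bg_total}, \code{ratio}, \code{chi2}, \code{p_value},
#'   \code{significant}; attributes \code{k}, \code{alpha},
#'   \code{correction}.
#' @export
enrich_kmers <- function(clip, control, k = 6L, alpha = 0.05,
                         correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(clip, "tag_set"), inherits(control, "tag_set"))
  if (length(clip) == 0L || length(control) == 0L)
    stop("both tag sets must be non-empty")
  kt_obs <- count_kmers(clip, k)
  kt_bg <- count_kmers(control, k)
  if (kt_bg$total_windows == 0L)
    stop("control set has zero valid windows at k = ", k)
  if (kt_obs$total_windows == 0L)
    stop("CLIP set has zero valid windows at k = ", k)
  kmers <- sort(union(names(kt_obs$counts), names(kt_bg$counts)))
  a <- as.numeric(kmer_count(kt_obs, kmers))
  c_ <- as.numeric(kmer_count(kt_bg, kmers))
  ot <- kt_obs$total_windows; bt <- kt_bg$total_windows
  chi <- chi2_two_by_two(a, ot, c_, bt)
  # ratio with +0.5 smoothing on all four cells when any cell is 0
  zero_cell <- a == 0 | c_ == 0 | a == ot | c_ == bt
  ratio <- ifelse(zero_cell,
                  ((a + 0.5) / (ot + 1)) / ((c_ + 0.5) / (bt + 1)),
                  (a / ot) / (c_ / bt))
  p_eff <- if (correction == "bonferroni")
    pmin(1, chi$p_value * 4^as.integer(k)) else chi$p_value
  res <- data.frame(kmer = kmers, obs_count = as.integer(a),
                    obs_total = ot, bg_count = as.integer(c_),
                    bg_total = bt, ratio = ratio, chi2 = chi$chi2,
                    p_value = chi$p_value,
                    significant = p_eff < alpha & ratio > 1,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$ratio, res$p_value, res$kmer), ]
  rownames(res) <- NULL
  structure(res, k = as.integer(k), alpha = alpha, correction = correction,
            class = c("kmer_enrichment", "data.frame"))
}

#' Filtered view of significant, enriched k-mers
#' @param results a \code{kmer_enrichment} data frame.
#' @return The rows with \code{significant} set (p below the level used in
#'   \code{\link{enrich_kmers}} and ratio > 1), in rank order.
#' @export
significant_kmers <- function(results) {
  stopifnot(inherits(results, "kmer_enrichment"))
  results[results$significant, , drop = FALSE]
}

#' Select the top-ranked enriched k-mers
#'
#' Ranking is by descending enrichment ratio, ties broken by ascending
#' p-value, then lexicographic k-mer.  Only significant results
#' (p < alpha and ratio > 1) are eligible; if fewer than \code{n} exist,
#' all are returned with a warning.
#'
#' @param results a \code{kmer_enrichment} data frame.
#' @param n number of motifs to keep, default 15.
#' @return The selected rows, in rank order.
#' @export
select_top_kmers <- function(results, n = 15L) {
  sig <- significant_kmers(results)
  sig <- sig[order(-sig$ratio, sig$p_value, sig$kmer), , drop = FALSE]
  if (nrow(sig) < n)
    warning(sprintf("only %d significant k-mers available (requested %d)",
                    nrow(sig), n))
  head(sig, n)
}

#' Build a position count matrix from tags containing top k-mers
#'
#' For every tag containing at least one of the top k-mers, the tag is
#' anchored at its first occurrence (leftmost position; on positional
#' ties, the earliest-ranked k-mer) and base counts are accumulated over
#' the window \code{[-flank, k + flank)} relative to the anchor (0-based
#' offsets).  Positions falling outside the tag contribute nothing, so
#' flank columns may sum to fewer than \code{n_sequences}; \code{N}
#' residues are never counted.
#'
#' @param tags a \code{tag_set}.
#' @param top_kmers character vector of k-mers in rank order (or a
#'   \code{kmer_enrichment} subset, whose \code{kmer} column is used);
#'   all must share one length.
#' @param flank nucleotides of context on each side of the k-mer window.
#' @return An object of class \code{logo_counts}: list with \code{counts}
#'   (4 x (k + 2 flank) matrix, rows A/C/G/U, columns named by offset),
#'   \code{n_sequences}, \code{k}, \code{flank}.
#' @export
build_logo_counts <- function(tags, top_kmers, flank = 0L) {
  stopifnot(inherits(tags, "tag_set"))
  if (is.data.frame(top_kmers)) top_kmers <- top_kmers$kmer
  top_kmers <- as.character(top_kmers)
  if (length(top_kmers) == 0L) stop("top_kmers must be non-empty")
  k <- unique(nchar(top_kmers))
  if (length(k) != 1L) stop("top_kmers must all have the same length")
  flank <- as.integer(flank)
  stopifnot(flank >= 0)
  offsets <- seq.int(-flank, k + flank - 1L)
  counts <- matrix(0L, nrow = 4L, ncol = length(offsets),
                   dimnames = list(c("A", "C", "G", "U"),
                                   as.character(offsets)))
  n_sequences <- 0L
  for (s in tags$seq) {
    pos <- vapply(top_kmers, function(m) regexpr(m, s, fixed = TRUE)[[1]],
                  integer(1))
    hit <- pos > 0L
    if (!any(hit)) next
    best <- min(pos[hit])
    n_sequences <- n_sequences + 1L
    anchor <- best - 1L                       # 0-based anchor
    at <- anchor + offsets + 1L               # 1-based residue positions
    inside <- at >= 1L & at <= nchar(s)
    ch <- substring(s, at[inside], at[inside])
    keep <- ch %in% rownames(counts)
    idx <- cbind(match(ch[keep], rownames(counts)),
                 which(inside)[keep])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1L
  }
  if (n_sequences == 0L)
    warning("no tag contains any of the top k-mers; empty matrix")
  structure(list(counts = counts, n_sequences = n_sequences,
                 k = as.integer(k), flank = flank),
            class = "logo_counts")
}

#' @export
print.logo_counts <- function(x, ...) {
  cat(sprintf("logo_counts: %d tags, k = %d, flank = %d\n",
              x$n_sequences, x$k, x$flank))
  print(x$counts)
  invisible(x)
}
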