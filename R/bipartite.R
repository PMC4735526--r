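# (A/U)AA core scanning and bipartite-site spacing analysis.
#
# A KH domain reads the consensus N(A/U)AAN; the scanner reports every
# (possibly overlapping) [AU]AA match.  A core's footprint is the core
# plus one 3' flanking nucleotide (4 nt, the length of single-stranded
# RNA a KH groove accommodates), truncated at the sequence end.  The
# separation between two cores is the number of intervening nucleotides
# between the upstream footprint end and the downstream core start; a
# bipartite site requires separation strictly greater than 15 (default
# min_separation = 16).  All coordinates are 0-based, half-open.

.CORE_FOOTPRINT <- 4L

.as_sequence <- function(seq) {
  if (inherits(seq, "tag_set")) {
    stopifnot(length(seq) == 1L)
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq
}

#' Scan a sequence for (A/U)AA core motifs
#'
#' Reports every match of \code{[AU]AA}, including overlapping ones, in
#' ascending position order.  Windows containing \code{N} never match.
#'
#' @param seq a single sequence (character, RNA alphabet) or a one-element
#'   \code{tag_set}.
#' @param footprint footprint length in nt assigned to each core (core +
#'   3' flank; default 4), truncated at the sequence end.
#' @return A data frame with columns \code{start} (0-based),
#'   \code{core} (the matched 3-mer) and \code{footprint_end}
#'   (exclusive, 0-based).
#' @examples
#' scan_cores("UAAAUAA")  # starts 0, 1, 4
#' @export
scan_cores <- function(seq, footprint = .CORE_FOOTPRINT) {
  seq <- .as_sequence(seq)
  stopifnot(footprint >= 3)
  n <- nchar(seq)
  m <- gregexpr("(?=[AU]AA)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), core = character(0),
                      footprint_end = integer(0),
                      stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L
  data.frame(start = starts,
             core = substring(seq, starts + 1L, starts + 3L),
             footprint_end = pmin(starts + as.integer(footprint), n),
             stringsAsFactors = FALSE)
}

#' Maximum separation between two cores of one sequence
#'
#' The separation of an ordered core pair is
#' \code{downstream$start - upstream$footprint_end}: the number of
#' intervening nucleotides between the upstream footprint and the
#' downstream core.  Returns the maximum over all ordered pairs, \code{NA}
#' when fewer than two hits exist, and possibly a negative value when only
#' overlapping cores exist (reported as-is).
#'
#' @param hits a data frame from \code{\link{scan_cores}} (ascending
#'   starts).
#' @return Integer separation, or \code{NA_integer_}.
#' @export
max_separation <- function(hits) {
  if (nrow(hits) < 2L) return(NA_integer_)
  # footprint_end is non-decreasing in start, so the maximum over ordered
  # pairs is last start minus first footprint end
  as.integer(hits$start[nrow(hits)] - hits$footprint_end[1L])
}

#' Find bipartite (A/U)AA sites in one sequence
#'
#' Enumerates every ordered core pair whose separation lies in
#' \code{[min_separation, max_separation_allowed]}.  The default
#' \code{min_separation = 16} encodes the requirement of strictly more
#' than 15 intervening nucleotides for a QUA1-KH dimer to engage both
#' cores of the same RNA; the default ceiling of 30 reflects the maximum
#' spacing at which in vivo tags show enrichment.  Set
#' \code{max_separation_allowed = NULL} for no ceiling.
#'
#' @inheritParams scan_cores
#' @param min_separation minimum intervening nt (>= 0), default 16.
#' @param max_separation_allowed maximum intervening nt, default 30;
#'   \code{NULL} for unlimited.
#' @return A data frame with columns \code{up_start}, \code{up_core},
#'   \code{down_start}, \code{down_core}, \code{separation}, ordered by
#'   \code{up_start} then \code{down_start}; attribute \code{has_site}
#'   flags a non-empty result.
#' @examples
#' sites <- find_bipartite_sites(strrep("UAAA", 8))
#' attr(sites, "has_site")
#' @export
find_bipartite_sites <- function(seq, min_separation = 16L,
                                 max_separation_allowed = 30L,
                                 footprint = .CORE_FOOTPRINT) {
  stopifnot(min_separation >= 0)
  if (is.null(max_separation_allowed)) max_separation_allowed <- Inf
  hits <- scan_cores(seq, footprint = footprint)
  out <- data.frame(up_start = integer(0), up_core = character(0),
                    down_start = integer(0), down_core = character(0),
                    separation = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) >= 2L) {
    pairs <- which(outer(hits$start, hits$start, "<"), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    sep <- hits$start[j] - hits$footprint_end[i]
    keep <- sep >= min_separation & sep <= max_separation_allowed
    if (any(keep)) {
      out <- data.frame(up_start = hits$start[i][keep],
                        up_core = hits$core[i][keep],
                        down_start = hits$start[j][keep],
                        down_core = hits$core[j][keep],
                        separation = as.integer(sep[keep]),
                        stringsAsFactors = FALSE)
      out <- out[order(out$up_start, out$down_start), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "has_site") <- nrow(out) > 0L
  out
}

#' Flag tags carrying at least one bipartite site
#'
#' @param tags a \code{tag_set}.
#' @inheritParams find_bipartite_sites
#' @return Logical vector, one element per tag.
#' @export
has_bipartite_site <- function(tags, min_separation = 16L,
                               max_separation_allowed = 30L,
                               footprint = .CORE_FOOTPRINT) {
  stopifnot(inherits(tags, "tag_set"))
  vapply(tags$seq, function(s)
    attr(find_bipartite_sites(s, min_separation, max_separation_allowed,
                              footprint), "has_site"),
    logical(1), USE.NAMES = FALSE)
}

#' Distribution of per-tag maximum core separations
#'
#' For each tag the maximum separation over ordered core pairs is
#' computed (\code{\link{max_separation}}).  Tags with fewer than two
#' cores are excluded from the histogram but counted in
#' \code{n_tags_scanned}, so normalized counts are per scanned tag and sum
#' to \code{n_tags_with_pair / n_tags_scanned}.  Separations are clamped
#' into \code{[0, max_distance]}; larger values fall into a single
#' overflow bin reported at distance \code{max_distance + 1}.
#'
#' @param tags a non-empty \code{tag_set}.
#' @param max_distance largest separation binned individually, default 50.
#' @param footprint core footprint (nt), default 4.
#' @return An object of class \code{spacing_distribution}: list with
#'   \code{bins} (data frame \code{distance}, \code{count},
#'   \code{normalized_count}; last row is the overflow bin),
#'   \code{n_tags_scanned}, \code{n_tags_with_pair}, \code{max_distance}.
#' @export
spacing_distribution <- function(tags, max_distance = 50L,
                                 footprint = .CORE_FOOTPRINT) {
  stopifnot(inherits(tags, "tag_set"))
  if (length(tags) == 0L) stop("empty tag set")
  max_distance <- as.integer(max_distance)
  seps <- vapply(tags$seq,
                 function(s) max_separation(scan_cores(s, footprint)),
                 integer(1), USE.NAMES = FALSE)
  with_pair <- !is.na(seps)
  seps <- pmax(0L, seps[with_pair])         # negative separations clamp to 0
  binned <- pmin(seps, max_distance + 1L)   # overflow bin
  distance <- c(0:max_distance, max_distance + 1L)
  count <- as.integer(tabulate(binned + 1L, nbins = max_distance + 2L))
  structure(list(bins = data.frame(distance = distance, count = count,
                                   normalized_count =
                                     count / length(tags)),
                 n_tags_scanned = length(tags),
                 n_tags_with_pair = sum(with_pair),
                 max_distance = max_distance),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat(sprintf(
    "spacing_distribution: %d/%d tags with a core pair; mode at %s nt\n",
    x$n_tags_with_pair, x$n_tags_scanned,
    if (x$n_tags_with_pair)
      x$bins$distance[which.max(x$bins$count)] else "-"))
  invisible(x)
}

#' Side-by-side spacing distributions for CLIP and control tags
#'
#' @param clip,control \code{tag_set}s.
#' @inheritParams spacing_distribution
#' @return A data frame with columns \code{distance},
#'   \code{clip_normalized}, \code{control_normalized} (last row is the
#'   overflow bin); attributes \code{clip} and \code{control} hold the
#'   full \code{\link{spacing_distribution}} objects.
#' @export
compare_spacing <- function(clip, control, max_distance = 50L,
                            footprint = .CORE_FOOTPRINT) {
  dc <- spacing_distribution(clip, max_distance, footprint)
  dg <- spacing_distribution(control, max_distance, footprint)
  structure(data.frame(distance = dc$bins$distance,
                       clip_normalized = dc$bins$normalized_count,
                       control_normalized = dg$bins$normalized_count),
            clip = dc, control = dg)
}
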