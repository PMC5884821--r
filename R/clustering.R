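#' Cluster clipped fragments at shared breakpoints
#'
#' Per orientation, fragments sorted by breakpoint are chained
#' single-linkage: a fragment joins the open cluster iff its breakpoint is
#' within `tol` (default 3 bp) of the previous member's breakpoint;
#' otherwise a new cluster opens. `linkage = "span"` instead bounds the
#' total span of a cluster by `tol`. The representative breakpoint is the
#' member median (lower of the two middles). Forward and backward clusters
#' are built independently.
#'
#' @param frags fragment data.frame from [extract_clips()]; one
#'   chromosome only.
#' @param tol breakpoint tolerance in bp (default 3).
#' @param linkage `"chain"` (default) or `"span"`.
#' @return list of clusters, each a list with `chrom`, `orientation`,
#'   `breakpoint0`, `members` (data.frame), `rescued` (data.frame, empty
#'   here), `support`; sorted by (breakpoint0, orientation with FWD < BWD).
#' @export
cluster_fragments <- function(frags, tol = 3L, linkage = c("chain", "span")) {
  linkage <- match.arg(linkage)
  if (nrow(frags) == 0L) return(list())
  if (length(unique(frags$chrom)) > 1L)
    stop("cluster_fragments expects fragments from a single chromosome")
  frags$breakpoint0 <- as.integer(frags$breakpoint0)
  clusters <- list()
  for (ori in c("FWD", "BWD")) {
    f <- frags[frags$orientation == ori, , drop = FALSE]
    if (nrow(f) == 0L) next
    f <- f[order(f$breakpoint0, f$qname), , drop = FALSE]
    bp <- f$breakpoint0
    grp <- integer(nrow(f))
    g <- 1L
    grp[1] <- g
    for (i in seq_len(nrow(f))[-1]) {
      base <- if (linkage == "chain") bp[i - 1L] else min(bp[grp == g])
      if (bp[i] - base > tol) g <- g + 1L
      grp[i] <- g
    }
    for (k in seq_len(g)) {
      m <- f[grp == k, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- list(
        chrom = m$chrom[1], orientation = ori,
        breakpoint0 = as.integer(.lower_median(m$breakpoint0)),
        members = m, rescued = .empty_rescued(),
        support = nrow(m))
    }
  }
  bps <- vapply(clusters, `[[`, integer(1), "breakpoint0")
  oris <- vapply(clusters, `[[`, character(1), "orientation")
  clusters[order(bps, match(oris, c("FWD", "BWD")))]
}

# lower of the two middles for even n
.lower_median <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

.empty_rescued <- function() {
  data.frame(chrom = character(), est_breakpoint0 = integer(),
             est_orientation = character(), seq = character(),
             qual = character(), qname = character(),
             anchor_pos0 = integer(), stringsAsFactors = FALSE)
}

#' Attach rescued unmapped reads to breakpoint clusters
#'
#' Each rescued read joins the nearest same-orientation cluster whose
#' representative breakpoint is within `tol` of the estimated breakpoint
#' (ties go to the smaller coordinate); reads matching no cluster are
#' pooled for de novo assembly. A read attaches to at most one cluster.
#'
#' @param clusters list from [cluster_fragments()].
#' @param rescued data.frame from [estimate_unmapped_breakpoints()].
#' @param tol attachment tolerance in bp; default 50 (the library insert
#'   sd), looser than the 3 bp clip rule because the estimate is soft.
#' @return list with `clusters` (updated, `support` refreshed) and
#'   `pooled` (unattached rescued reads).
#' @export
attach_unmapped <- function(clusters, rescued, tol = 50L) {
  if (length(clusters) == 0L || nrow(rescued) == 0L)
    return(list(clusters = clusters, pooled = rescued))
  bps <- vapply(clusters, `[[`, integer(1), "breakpoint0")
  oris <- vapply(clusters, `[[`, character(1), "orientation")
  pooled_idx <- integer()
  for (i in seq_len(nrow(rescued))) {
    cand <- which(oris == rescued$est_orientation[i])
    if (length(cand)) {
      d <- abs(bps[cand] - as.integer(rescued$est_breakpoint0[i]))
      ok <- cand[d <= tol]
      if (length(ok)) {
        dd <- abs(bps[ok] - as.integer(rescued$est_breakpoint0[i]))
        best <- ok[dd == min(dd)]
        best <- best[which.min(bps[best])]  # tie: smaller coordinate
        clusters[[best]]$rescued <- rbind(clusters[[best]]$rescued,
                                          rescued[i, , drop = FALSE])
        next
      }
    }
    pooled_idx <- c(pooled_idx, i)
  }
  for (k in seq_along(clusters))
    clusters[[k]]$support <- nrow(clusters[[k]]$members) +
      nrow(clusters[[k]]$rescued)
  list(clusters = clusters, pooled = rescued[pooled_idx, , drop = FALSE])
}
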