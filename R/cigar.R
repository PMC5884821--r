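#' CIGAR utilities
#'
#' Small vectorised CIGAR helpers. Query-consuming operations are
#' M, I, S, =, X; reference-consuming operations are M, D, N, =, X.
#'
#' @param cigars character vector of CIGAR strings ("*" allowed).
#' @return `explode_cigar()`: a data.frame with columns `idx` (index into
#'   `cigars`), `op` (single character) and `len` (integer).
#' @examples
#' explode_cigar(c("100M61S", "61S100M"))
#' cigar_ref_span("90M60S")   # 90
#' cigar_query_len("20S120M21S")  # 161
#' @export
explode_cigar <- function(cigars) {
  stopifnot(is.character(cigars))
  hits <- gregexpr("\\d+[MIDNSHP=X]", cigars)
  toks <- regmatches(cigars, hits)
  nt <- lengths(toks)
  nt[cigars == "*" | is.na(cigars)] <- 0L
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0L) {
    return(data.frame(idx = integer(), op = character(), len = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(idx = rep.int(seq_along(cigars), nt),
             op = substr(flat, nchar(flat), nchar(flat)),
             len = as.integer(substr(flat, 1L, nchar(flat) - 1L)),
             stringsAsFactors = FALSE)
}

.cigar_span <- function(cigars, ops) {
  ex <- explode_cigar(cigars)
  out <- integer(length(cigars))
  keep <- ex$op %in% ops
  if (any(keep)) {
    agg <- tapply(ex$len[keep], ex$idx[keep], sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

#' @rdname explode_cigar
#' @export
cigar_ref_span <- function(cigars) .cigar_span(cigars, c("M", "D", "N", "=", "X"))

#' @rdname explode_cigar
#' @export
cigar_query_len <- function(cigars) .cigar_span(cigars, c("M", "I", "S", "=", "X"))

# leading/trailing soft-clip lengths (0 when absent)
.clip_lens <- function(cigars) {
  lead <- rep.int(0L, length(cigars))
  trail <- rep.int(0L, length(cigars))
  ml <- regmatches(cigars, regexpr("^\\d+S", cigars))
  has <- grepl("^\\d+S", cigars)
  lead[has] <- as.integer(sub("S", "", ml))
  mt <- regmatches(cigars, regexpr("\\d+S$", cigars))
  hast <- grepl("\\d+S$", cigars)
  trail[hast] <- as.integer(sub("S", "", mt))
  # a CIGAR that is a single soft clip ("61S") would be both; treat as lead
  both_same <- has & hast & !grepl("[MIDN=X]", cigars)
  trail[both_same] <- 0L
  data.frame(lead = lead, trail = trail)
}
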