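# Internal helpers shared across modules.

#' @importFrom stats setNames
NULL

# Coordinates are 0-based half-open [start, end) everywhere inside the
# package; GRanges (1-based closed) only at the rtracklayer boundary.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand` and `name`.
#' @return A [GenomicRanges::GRanges] object (1-based closed coordinates).
#' @keywords internal
.granges_from_intervals <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand   = strand
  )
  if ("name" %in% names(df)) gr$name <- df$name
  gr
}

.intervals_from_granges <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  if (!is.null(gr$name)) df$name <- gr$name
  df
}

# Point positions (single bases, 0-based) as GRanges.
.granges_from_positions <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
}

.assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Run code with a locally seeded RNG, restoring the caller's stream after.
# All module randomness flows through this, keyed off the config seed plus a
# fixed per-stage offset, so stages are reproducible independent of call order.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
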