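## Leakage-safe partitioning: records (not segments) are assigned to
## training / validation / test, so all segments of a record share a
## partition. The split happens before augmentation or balancing, and the
## partition tags drive the hard leakage guards downstream.

#' Split a segment set into train/validation/test by record
#'
#' Records are shuffled under the seed and assigned so the cumulative
#' segment counts approximate the requested fractions. Every record's
#' segments land in exactly one partition.
#'
#' @param segs A labelled [segment_set()].
#' @param fractions Named numeric vector over
#'   `c(training, validation, test)` summing to 1.
#' @param seed Integer seed.
#' @return Named list of [segment_set()]s tagged `"training"`,
#'   `"validation"`, `"test"` (empty partitions are dropped).
#' @export
split_by_records <- function(segs,
                             fractions = c(training = 0.6,
                                           validation = 0.2, test = 0.2),
                             seed = 1L) {
  stopifnot(inherits(segs, "segment_set"))
  if (abs(sum(fractions) - 1) > 1e-9)
    abort_param("fractions must sum to 1")
  recs <- unique(segs$provenance$record_id)
  set.seed(seed)
  recs <- sample(recs)
  n_seg <- vapply(recs, function(r)
    sum(segs$provenance$record_id == r), 0L)
  cum <- cumsum(n_seg) / sum(n_seg)
  bounds <- cumsum(fractions)
  part_of <- cut(cum, breaks = c(0, bounds[-length(bounds)], 1 + 1e-9),
                 labels = names(fractions), include.lowest = TRUE)
  out <- list()
  for (p in names(fractions)) {
    rp <- recs[part_of == p]
    if (!length(rp)) next
    idx <- which(segs$provenance$record_id %in% rp)
    out[[p]] <- subset_segments(segs, idx, partition = p)
  }
  out
}
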