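# Demultiplexing: a variant detected in one horizontal and one vertical
# pool decodes to the single well in their intersection; multiple carriers
# produce several pool hits per orientation and hence a candidate set.

#' Demultiplex detected pool calls to candidate wells
#'
#' Groups detected calls by variant, splits pool hits by orientation, and
#' decodes every (horizontal, vertical) pair through the design. Status is
#' `unique` (one candidate well), `ambiguous` (both orientations hit but not
#' exactly one candidate), `orphan_h`/`orphan_v` (hits in only one
#' orientation), or `hyper` when more than `max_pool_hits` pools fire in one
#' orientation (likely systematic artifact; excluded from decoding).
#'
#' @param detected Detected calls ([call_pool_variants()]).
#' @param design The [build_design()] used for pooling.
#' @param max_pool_hits Per-orientation hit count above which a variant is
#'   flagged `hyper` (default 3).
#'
#' @return `data.frame` with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, `n_h`, `n_v`, `h_pools`, `v_pools` (`;`-joined), `status`,
#'   `candidates` (`;`-joined well ids).
#' @export
demultiplex <- function(detected, design, max_pool_hits = 3L) {
  cols <- c("chrom", "pos", "ref", "alt", "n_h", "n_v", "h_pools",
            "v_pools", "status", "candidates")
  if (!nrow(detected)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n_h = integer(0), n_v = integer(0),
                      h_pools = character(0), v_pools = character(0),
                      status = character(0), candidates = character(0))
    return(out)
  }
  unknown <- setdiff(unique(detected$pool_id), design$pools$pool_id)
  if (length(unknown))
    stop("calls reference pool(s) absent from the design: ",
         paste(unknown, collapse = ", "))
  key <- paste(detected$chrom, detected$pos, detected$ref, detected$alt,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(detected)), factor(key, unique(key))),
                 function(ii) {
    d <- detected[ii, ]
    hp <- sort(unique(d$pool_id[d$orientation == "horizontal"]))
    vp <- sort(unique(d$pool_id[d$orientation == "vertical"]))
    if (length(hp) > max_pool_hits || length(vp) > max_pool_hits) {
      status <- "hyper"; cand <- character(0)
    } else if (!length(hp) && !length(vp)) {
      status <- "absent"; cand <- character(0)
    } else if (!length(vp)) {
      status <- "orphan_h"; cand <- character(0)
    } else if (!length(hp)) {
      status <- "orphan_v"; cand <- character(0)
    } else {
      # all pairwise decodes at once: wells lying in a hit pool of each
      # orientation (equivalent to decoding every (h, v) pair)
      w <- design$wells[design$wells$h_pool %in% hp &
                          design$wells$v_pool %in% vp, ]
      cand <- sort(w$well)
      status <- if (length(cand) == 1L) "unique" else "ambiguous"
    }
    data.frame(chrom = d$chrom[1], pos = d$pos[1], ref = d$ref[1],
               alt = d$alt[1], n_h = length(hp), n_v = length(vp),
               h_pools = paste(hp, collapse = ";"),
               v_pools = paste(vp, collapse = ";"),
               status = status, candidates = paste(cand, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$alt), cols]
  rownames(out) <- NULL
  out
}

#' Score screen performance against simulation truth
#'
#' @param decoded A [demultiplex()] table.
#' @param truth Carrier-level truth table.
#' @param lines Line manifest with wells (`line_id`, `plate`, `row`,
#'   `column`), used to resolve carrier wells.
#'
#' @return List of class `screen_performance`: `sensitivity` (fraction of
#'   truth variants decoded with any non-absent status), `unique_rate` and
#'   `ambiguity_rate` (fractions of decoded variants), and
#'   `false_assignment_rate` (fraction of unique decodes naming a
#'   non-carrier well), plus the underlying counts.
#' @export
screen_performance <- function(decoded, truth, lines) {
  if (is.null(truth) || !nrow(truth)) stop("truth table is empty")
  tkey <- unique(paste(truth$chrom, truth$pos, truth$ref, truth$alt,
                       sep = "\r"))
  dkey <- paste(decoded$chrom, decoded$pos, decoded$ref, decoded$alt,
                sep = "\r")
  found <- tkey %in% dkey[decoded$status != "absent"]
  sens <- mean(found)

  n_dec <- nrow(decoded)
  unique_rate <- if (n_dec) mean(decoded$status == "unique") else 0
  ambiguity_rate <- if (n_dec) mean(decoded$status == "ambiguous") else 0

  lw <- lines
  lw$well <- well_id(lw$plate, lw$row, lw$column)
  carrier_wells <- split(lw$well[match(truth$line_id, lw$line_id)],
                         paste(truth$chrom, truth$pos, truth$ref, truth$alt,
                               sep = "\r"))
  uq <- decoded[decoded$status == "unique", ]
  if (nrow(uq)) {
    uk <- paste(uq$chrom, uq$pos, uq$ref, uq$alt, sep = "\r")
    false_assign <- vapply(seq_len(nrow(uq)), function(i) {
      cw <- carrier_wells[[uk[i]]]
      is.null(cw) || !(uq$candidates[i] %in% cw)
    }, logical(1))
    far <- mean(false_assign)
  } else far <- 0
  structure(list(
    sensitivity = sens, unique_rate = unique_rate,
    ambiguity_rate = ambiguity_rate, false_assignment_rate = far,
    n_truth_variants = length(tkey), n_decoded = n_dec,
    n_unique = sum(decoded$status == "unique")
  ), class = "screen_performance")
}

#' @export
print.screen_performance <- function(x, ...) {
  cat("<screen_performance> ", x$n_truth_variants, " truth variants, ",
      x$n_decoded, " decoded\n", sep = "")
  cat(sprintf("  sensitivity          %.3f\n", x$sensitivity))
  cat(sprintf("  unique decode rate   %.3f\n", x$unique_rate))
  cat(sprintf("  ambiguity rate       %.3f\n", x$ambiguity_rate))
  cat(sprintf("  false assignment     %.3f\n", x$false_assignment_rate))
  invisible(x)
}

#' @rdname screen_performance
#' @export
as.data.frame.screen_performance <- function(x, ...) {
  data.frame(metric = c("sensitivity", "unique_rate", "ambiguity_rate",
                        "false_assignment_rate"),
             value = c(x$sensitivity, x$unique_rate, x$ambiguity_rate,
                       x$false_assignment_rate))
}
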