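# Bidimensional pooling of 96-well source plates.
#
# Horizontal pools combine one plate row across a block of 4 consecutive
# plates (up to 4 plates x 12 columns = 48 samples). Vertical pools combine
# one plate column across a triplet of plates spaced 4 apart within an
# aligned block of 12 plates ({b+i, b+i+4, b+i+8}, i = 1..4; up to 3 plates
# x 8 rows = 24 samples). Because each 4-plate block intersects each triplet
# in exactly one plate, the (horizontal, vertical) pool pair of a well
# identifies the well uniquely, which is what makes the design decodable.

.PLATE_ROWS <- LETTERS[1:8]
.PLATE_COLS <- 1:12

well_id <- function(plate, row, column) {
  sprintf("P%03d-%s%02d", plate, row, column)
}

#' Build the bidimensional pooling design
#'
#' Lays out `n_plates` 96-well plates (rows A-H, columns 1-12) and assigns
#' every well to exactly one horizontal and one vertical pool. For complete
#' blocks, horizontal pools hold 48 samples (one row across 4 consecutive
#' plates) and vertical pools hold 24 (one column across 3 plates spaced 4
#' apart). Trailing plates that do not complete a block form reduced pools;
#' these are flagged `complete = FALSE` in the pool table rather than
#' refused, and unique decodability is preserved.
#'
#' @param n_plates Number of source plates (>= 1).
#'
#' @return Object of class `pooling_design`: list with `n_plates`, `wells`
#'   (one row per well: `plate`, `row`, `column`, `well`, `h_pool`,
#'   `v_pool`), and `pools` (one row per pool: `pool_id`, `orientation`,
#'   `n_members`, `complete`).
#' @export
#' @examples
#' d <- build_design(12)
#' table(d$pools$orientation)
build_design <- function(n_plates) {
  if (!is.numeric(n_plates) || length(n_plates) != 1L || n_plates < 1)
    stop("n_plates must be a positive integer")
  n_plates <- as.integer(n_plates)

  wells <- expand.grid(column = .PLATE_COLS, row = .PLATE_ROWS,
                       plate = seq_len(n_plates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells <- wells[, c("plate", "row", "column")]

  # horizontal: blocks of 4 consecutive plates
  hb <- (wells$plate - 1L) %/% 4L
  h_first <- hb * 4L + 1L
  h_last <- pmin(h_first + 3L, n_plates)
  wells$h_pool <- sprintf("H-r%s-p%02d.%02d", wells$row, h_first, h_last)

  # vertical: triplets {i, i+4, i+8} within aligned blocks of 12 plates
  vb <- (wells$plate - 1L) %/% 12L
  i <- (wells$plate - vb * 12L - 1L) %% 4L + 1L
  trip_key <- paste(vb, i)
  trip_plates <- lapply(unique(trip_key), function(k) {
    kk <- as.integer(strsplit(k, " ")[[1]])
    p <- kk[1] * 12L + kk[2] + c(0L, 4L, 8L)
    p[p <= n_plates]
  })
  names(trip_plates) <- unique(trip_key)
  trip_id <- vapply(trip_plates, function(p)
    paste(sprintf("%02d", p), collapse = "."), character(1))
  wells$v_pool <- sprintf("V-c%02d-p%s", wells$column, trip_id[trip_key])

  wells$well <- well_id(wells$plate, wells$row, wells$column)
  wells <- wells[, c("plate", "row", "column", "well", "h_pool", "v_pool")]

  hp <- as.data.frame(table(wells$h_pool), stringsAsFactors = FALSE)
  vp <- as.data.frame(table(wells$v_pool), stringsAsFactors = FALSE)
  pools <- rbind(
    data.frame(pool_id = hp$Var1, orientation = "horizontal",
               n_members = hp$Freq, complete = hp$Freq == 48L),
    data.frame(pool_id = vp$Var1, orientation = "vertical",
               n_members = vp$Freq, complete = vp$Freq == 24L)
  )
  pools <- pools[order(pools$orientation, pools$pool_id), ]
  rownames(pools) <- NULL

  structure(list(n_plates = n_plates, wells = wells, pools = pools),
            class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  nh <- sum(x$pools$orientation == "horizontal")
  nv <- sum(x$pools$orientation == "vertical")
  cat("<pooling_design> ", x$n_plates, " plates, ", nrow(x$wells),
      " wells\n  ", nh, " horizontal pools (<= 48 samples), ",
      nv, " vertical pools (<= 24 samples)\n", sep = "")
  if (any(!x$pools$complete))
    cat("  ", sum(!x$pools$complete),
        " reduced pool(s) from an incomplete trailing block\n", sep = "")
  invisible(x)
}

#' @export
summary.pooling_design <- function(object, ...) {
  p <- object$pools
  out <- aggregate(n_members ~ orientation, p,
                   function(v) c(pools = length(v), min = min(v), max = max(v)))
  cat("<pooling_design summary>\n")
  print(do.call(data.frame, out))
  invisible(out)
}

# long membership table (pool_id, orientation, plate, row, column)
design_members <- function(design) {
  w <- design$wells
  rbind(
    data.frame(pool_id = w$h_pool, orientation = "horizontal",
               plate = w$plate, row = w$row, column = w$column),
    data.frame(pool_id = w$v_pool, orientation = "vertical",
               plate = w$plate, row = w$row, column = w$column)
  )
}

#' Decode a pool pair to a well
#'
#' Returns the unique well lying in both pools' member sets, i.e. the sample
#' that explains a variant seen in one horizontal and one vertical pool.
#'
#' @param h_pool,v_pool Pool ids from `design$pools`.
#' @param design A [build_design()] result.
#'
#' @return One-row `data.frame` (`plate`, `row`, `column`, `well`), or `NULL`
#'   when the member sets do not intersect. An intersection larger than one
#'   well violates the design invariant and is an error.
#' @export
decode_address <- function(h_pool, v_pool, design) {
  ids <- design$pools$pool_id
  if (!h_pool %in% ids) stop("unknown horizontal pool: ", h_pool)
  if (!v_pool %in% ids) stop("unknown vertical pool: ", v_pool)
  hit <- design$wells[design$wells$h_pool == h_pool &
                        design$wells$v_pool == v_pool, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  if (nrow(hit) > 1L)
    stop("design invariant violated: pools ", h_pool, " and ", v_pool,
         " intersect in ", nrow(hit), " wells")
  rownames(hit) <- NULL
  hit[, c("plate", "row", "column", "well")]
}

#' Verify a pooling design
#'
#' Checks the design invariants: every well in exactly one pool per
#' orientation, pool size limits (48 horizontal / 24 vertical), and
#' injectivity of the (horizontal, vertical) pair over wells.
#'
#' @param design A `pooling_design` (built or imported).
#' @return `data.frame` with columns `violation` and `detail`; zero rows when
#'   the design is valid.
#' @export
verify_design <- function(design) {
  v <- list()
  add <- function(violation, detail)
    v[[length(v) + 1L]] <<- data.frame(violation = violation, detail = detail)

  m <- design$members
  if (is.null(m)) m <- design_members(design)
  m$well <- well_id(m$plate, m$row, m$column)

  for (orient in c("horizontal", "vertical")) {
    mm <- m[m$orientation == orient, ]
    cnt <- table(mm$well)
    dup <- names(cnt)[cnt > 1L]
    if (length(dup))
      add(paste0("duplicate ", orient, " membership"),
          paste(dup, collapse = ";"))
    all_wells <- unique(m$well)
    missing <- setdiff(all_wells, mm$well)
    if (length(missing))
      add(paste0("missing ", orient, " membership"),
          paste(missing, collapse = ";"))
    size <- table(mm$pool_id)
    cap <- if (orient == "horizontal") 48L else 24L
    over <- names(size)[size > cap]
    if (length(over))
      add(paste0(orient, " pool over capacity"), paste(over, collapse = ";"))
  }

  # injectivity of (h, v) -> well over wells having one pool per orientation
  h <- m[m$orientation == "horizontal", ]
  vt <- m[m$orientation == "vertical", ]
  pair <- merge(h[, c("well", "pool_id")], vt[, c("well", "pool_id")],
                by = "well", suffixes = c(".h", ".v"))
  key <- paste(pair$pool_id.h, pair$pool_id.v)
  cnt <- table(key)
  clash <- names(cnt)[cnt > 1L]
  for (k in clash)
    add("injectivity violation",
        paste0("(", k, ") -> ",
               paste(sort(pair$well[key == k]), collapse = ";")))

  if (!length(v))
    return(data.frame(violation = character(0), detail = character(0)))
  do.call(rbind, v)
}

#' Export / import a pooling design as TSV
#'
#' One line per pool member with columns `pool_id`, `orientation`, `plate`,
#' `row`, `column`, so the design can be replayed by liquid handlers or
#' rebuilt from disk.
#'
#' @param design A `pooling_design`.
#' @param path TSV path.
#' @return `write_design_tsv` returns `path` invisibly; `read_design_tsv`
#'   returns a `pooling_design` (verified on load).
#' @export
write_design_tsv <- function(design, path) {
  m <- design_members(design)
  m <- m[order(m$orientation, m$pool_id, m$plate, m$row, m$column), ]
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pool_id", "orientation", "plate", "row", "column")
  if (!all(need %in% names(m)))
    stop("design TSV must have columns ", paste(need, collapse = ", "))
  h <- m[m$orientation == "horizontal", ]
  vt <- m[m$orientation == "vertical", ]
  wells <- merge(
    data.frame(plate = h$plate, row = h$row, column = h$column,
               h_pool = h$pool_id),
    data.frame(plate = vt$plate, row = vt$row, column = vt$column,
               v_pool = vt$pool_id),
    by = c("plate", "row", "column"), all = TRUE
  )
  wells$well <- well_id(wells$plate, wells$row, wells$column)
  wells <- wells[order(wells$plate, wells$row, wells$column),
                 c("plate", "row", "column", "well", "h_pool", "v_pool")]
  sizes <- table(m$pool_id)
  orient <- m$orientation[match(names(sizes), m$pool_id)]
  pools <- data.frame(pool_id = names(sizes), orientation = orient,
                      n_members = as.integer(sizes),
                      complete = as.integer(sizes) ==
                        ifelse(orient == "horizontal", 48L, 24L))
  pools <- pools[order(pools$orientation, pools$pool_id), ]
  rownames(pools) <- rownames(wells) <- NULL
  d <- structure(list(n_plates = max(m$plate), wells = wells, pools = pools,
                      members = m[, need]),
                 class = "pooling_design")
  bad <- verify_design(d)
  if (nrow(bad))
    stop("imported design violates invariants: ",
         paste(bad$violation, collapse = "; "))
  d
}
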