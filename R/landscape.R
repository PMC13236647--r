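# Landscape-pattern metrics on class rasters, following the FRAGSTATS
# conventions: largest patch index (LPI, %), patch density (PD, patches
# per 100 ha), edge density (ED, m/ha, landscape border excluded), and
# Shannon's diversity index (SHDI, natural log).

#' Delineate patches in a class raster
#'
#' Labels connected components of equal-class cells under 8-neighbor
#' (default, the FRAGSTATS convention) or 4-neighbor connectivity.
#' Nodata cells belong to no patch.
#'
#' @param r A [gm_raster()] of integer classes.
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return A `patch_set`: list with `patches` (tibble: `patch_id`,
#'   `class`, `n_cells`, `area` m^2, `edge_length` m of class boundary
#'   the patch touches), `labels` (matrix of patch ids, 0 = nodata),
#'   `landscape_area` (m^2 of non-nodata cells), `cell_size`,
#'   `connectivity`.
#' @export
delineate_patches <- function(r, connectivity = 8) {
  stopifnot(inherits(r, "gm_raster"))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- v != r$nodata & !is.na(v)
  if (!any(valid)) abort("Raster contains no non-nodata cells.")
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  labels <- matrix(0L, nr, nc)
  next_id <- 0L
  idx_all <- which(valid)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    next_id <- next_id + 1L
    cls <- v[start]
    frontier <- start
    labels[start] <- next_id
    while (length(frontier) > 0) {
      fr <- ((frontier - 1L) %% nr) + 1L
      fc <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (o in offs) {
        rr <- fr + o[1]; cc <- fc + o[2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        cand <- (cc[ok] - 1L) * nr + rr[ok]
        cand <- cand[labels[cand] == 0L & valid[cand] & v[cand] == cls]
        if (length(cand) > 0) {
          cand <- unique(cand)
          labels[cand] <- next_id
          nxt <- c(nxt, cand)
        }
      }
      frontier <- nxt
    }
  }
  cs <- r$cell_size
  # Class-boundary edges: shared sides between two non-nodata cells of
  # different classes. Edges to nodata or to the landscape border are not
  # counted (border excluded).
  edge_pairs <- function() {
    segs <- list()
    if (nr > 1) {
      a <- v[-nr, , drop = FALSE]; b <- v[-1, , drop = FALSE]
      va <- valid[-nr, , drop = FALSE]; vb <- valid[-1, , drop = FALSE]
      la <- labels[-nr, , drop = FALSE]; lb <- labels[-1, , drop = FALSE]
      d <- va & vb & (a != b)
      segs$v <- list(l1 = la[d], l2 = lb[d])
    }
    if (nc > 1) {
      a <- v[, -nc, drop = FALSE]; b <- v[, -1, drop = FALSE]
      va <- valid[, -nc, drop = FALSE]; vb <- valid[, -1, drop = FALSE]
      la <- labels[, -nc, drop = FALSE]; lb <- labels[, -1, drop = FALSE]
      d <- va & vb & (a != b)
      segs$h <- list(l1 = la[d], l2 = lb[d])
    }
    segs
  }
  segs <- edge_pairs()
  l1 <- c(segs$v$l1, segs$h$l1)
  l2 <- c(segs$v$l2, segs$h$l2)
  edge_per_patch <- numeric(next_id)
  if (length(l1) > 0) {
    tab <- table(factor(c(l1, l2), levels = seq_len(next_id)))
    edge_per_patch <- as.numeric(tab) * cs
  }
  counts <- as.integer(table(factor(labels[labels > 0L], levels = seq_len(next_id))))
  cls_of <- vapply(seq_len(next_id), function(id) v[match(id, labels)], v[idx_all[1]])
  patches <- tibble(
    patch_id = seq_len(next_id),
    class = cls_of,
    n_cells = counts,
    area = counts * cs^2,
    edge_length = edge_per_patch
  )
  structure(
    list(
      patches = patches,
      labels = labels,
      landscape_area = sum(valid) * cs^2,
      cell_size = cs,
      connectivity = connectivity,
      total_edge = if (length(l1) > 0) length(l1) * cs else 0
    ),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf(
    "<patch_set> %d patches, %d classes, landscape %g ha (%d-connectivity)\n",
    nrow(x$patches), length(unique(x$patches$class)),
    x$landscape_area / 1e4, x$connectivity
  ))
  invisible(x)
}

#' Largest patch index
#'
#' Percentage of the landscape occupied by the single largest patch.
#'
#' @param p A [delineate_patches()] result.
#' @return A percentage in (0, 100\].
#' @export
lpi <- function(p) {
  stopifnot(inherits(p, "patch_set"))
  if (nrow(p$patches) == 0) abort("Empty patch set.")
  100 * max(p$patches$area) / p$landscape_area
}

#' Patch density
#'
#' Number of patches per 100 hectares of landscape.
#'
#' @inheritParams lpi
#' @return Patches per 100 ha.
#' @export
patch_density <- function(p) {
  stopifnot(inherits(p, "patch_set"))
  if (p$landscape_area <= 0) abort("Zero landscape area.")
  nrow(p$patches) / p$landscape_area * 1e4 * 100
}

#' Edge density
#'
#' Total length of class boundaries (shared sides between cells of
#' different classes; the landscape border is excluded) per hectare.
#'
#' @inheritParams lpi
#' @return Meters of edge per hectare.
#' @export
edge_density <- function(p) {
  stopifnot(inherits(p, "patch_set"))
  if (p$landscape_area <= 0) abort("Zero landscape area.")
  p$total_edge / (p$landscape_area / 1e4)
}

#' Shannon's diversity index
#'
#' `-sum(p_k log p_k)` over class area proportions, in nats. Depends only
#' on class composition, not on patch arrangement.
#'
#' @param r A [gm_raster()] of classes, or a [delineate_patches()] result.
#' @return SHDI >= 0.
#' @export
shdi <- function(r) {
  if (inherits(r, "patch_set")) {
    areas <- tapply(r$patches$area, r$patches$class, sum)
  } else {
    stopifnot(inherits(r, "gm_raster"))
    v <- r$values[r$values != r$nodata & !is.na(r$values)]
    if (length(v) == 0) abort("Raster contains no non-nodata cells.")
    areas <- table(v)
  }
  pk <- as.numeric(areas) / sum(areas)
  -sum(pk * log(pk))
}

#' All four landscape metrics of a class raster
#'
#' @param r A [gm_raster()] of classes.
#' @param connectivity Passed to [delineate_patches()].
#' @return A one-row tibble: `lpi`, `pd`, `ed`, `shdi`, `n_patches`.
#' @export
landscape_metrics <- function(r, connectivity = 8) {
  p <- delineate_patches(r, connectivity)
  tibble(
    lpi = lpi(p),
    pd = patch_density(p),
    ed = edge_density(p),
    shdi = shdi(r),
    n_patches = nrow(p$patches)
  )
}
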