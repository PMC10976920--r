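#' Extract the lung fields from a chest volume
#'
#' Rule-based segmentation: threshold at -320 HU, discard air components
#' touching the volume border, keep the two largest internal components, fill
#' interior holes, and assign left/right by centroid x-coordinate.
#'
#' @param volume an `fg_volume` in HU.
#' @param threshold_hu air/tissue threshold (default -320).
#' @return an `fg_mask` with left/right lung labels.
#' @export
extract_lung_mask <- function(volume, threshold_hu = -320) {
  stopifnot(inherits(volume, "fg_volume"))
  d <- dim(volume$data)
  air <- volume$data < threshold_hu
  lab <- array(cpp_cc_label(as.logical(air), d, 6L), d)
  ncomp <- attr(lab, "n_components")
  if (is.null(ncomp)) ncomp <- max(lab)
  if (ncomp == 0) stop("empty mask: no sub-threshold voxels")
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  internal <- setdiff(which(sizes > 0), border)
  if (length(internal) < 2) stop("lungs not separable: fewer than two internal air components")
  keep <- internal[order(sizes[internal], decreasing = TRUE)][1:2]

  lung <- array(0L, d)
  cx <- numeric(2)
  for (k in 1:2) {
    comp <- lab == keep[k]
    # fill holes: background components of the complement not touching border
    inv <- array(cpp_cc_label(!comp, d, 6L), d)
    bg <- unique(c(inv[1, , ], inv[d[1], , ], inv[, 1, ], inv[, d[2], ],
                   inv[, , 1], inv[, , d[3]]))
    comp <- comp | (inv > 0 & !(inv %in% bg))
    lung[comp] <- k
    cx[k] <- mean(arrayInd(which(comp), d)[, 1])
  }
  # left = smaller centroid x (x runs left -> right)
  if (cx[1] > cx[2]) lung <- array(c(0L, 2L, 1L)[lung + 1L], d)
  fg_mask(lung > 0, volume$spacing, volume$origin, lung = lung)
}

#' Partition a lung mask into the 36-region geometric atlas
#'
#' Per lung independently: (a) the axial extent is split into apical, middle
#' and basal slabs at the 1/3 and 2/3 voxel-count quantiles of the lung's
#' z-coordinates; (b) each slab is split into anterior/posterior halves at
#' the slab's median y-coordinate; (c) each of the 12 cells per lung is split
#' into peripheral, middle and central shells by tertiles of the voxel's
#' Euclidean distance (mm) to the lung boundary, ties breaking toward the
#' more central shell. This yields 18 regions per lung, 36 in total; regions
#' may legitimately be empty and are then flagged absent.
#'
#' @param mask `fg_mask` with left/right lung labels (see
#'   [extract_lung_mask()]).
#' @return an `fg_atlas`: label volume (values 1-36, 0 outside) plus a
#'   region table.
#' @export
build_atlas <- function(mask) {
  stopifnot(inherits(mask, "fg_mask"))
  if (is.null(mask$lung)) stop("mask must carry left/right lung labels")
  d <- dim(mask$data)
  labels <- array(0L, d)
  for (side in 1:2) {
    lm <- mask$lung == side
    n <- sum(lm)
    if (n == 0) next
    if (n < 36) stop("lung with fewer than 36 voxels cannot be parcellated")
    dist <- array(cpp_edt(lm, d, mask$spacing), d)
    idx <- which(lm)
    co <- arrayInd(idx, d)
    slab <- count_split(co[, 3], 3)                 # 1 = low z (inferior)
    axial <- 4L - slab                              # 1 = apical, 3 = basal
    for (ab in 1:3) {
      insl <- axial == ab
      if (!any(insl)) next
      half <- count_split(co[insl, 2], 2)           # 1 = low y (posterior)
      coronal <- 3L - half                          # 1 = anterior, 2 = posterior
      for (cb in 1:2) {
        cell <- which(insl)[coronal == cb]
        if (length(cell) == 0) next
        dv <- dist[idx[cell]]
        t12 <- quantile(dv, c(1 / 3, 2 / 3), type = 7, names = FALSE)
        shell <- ifelse(dv < t12[1], 1L, ifelse(dv < t12[2], 2L, 3L))
        rid <- (side - 1L) * 18L + (ab - 1L) * 6L + (cb - 1L) * 3L + shell
        labels[idx[cell]] <- rid
      }
    }
  }
  atlas <- structure(list(labels = labels, spacing = mask$spacing,
                          origin = mask$origin,
                          table = region_table(labels)),
                     class = "fg_atlas")
  atlas
}

# split integer coordinates into nearly equal-count ordered bins; boundaries
# chosen at the coordinate whose cumulative count is nearest the ideal split,
# so bin counts deviate from n/k by at most half the largest single-slice count
count_split <- function(coord, k) {
  tab <- table(coord)
  vals <- as.integer(names(tab))
  cum <- cumsum(as.integer(tab))
  n <- cum[length(cum)]
  bounds <- integer(k - 1)
  for (j in seq_len(k - 1)) {
    ideal <- n * j / k
    bounds[j] <- vals[which.min(abs(cum - ideal))]
  }
  out <- rep.int(k, length(coord))
  for (j in rev(seq_len(k - 1))) out[coord <= bounds[j]] <- j
  as.integer(out)
}

region_table <- function(labels) {
  cnt <- tabulate(labels[labels > 0], nbins = 36L)
  grid <- expand.grid(shell = 1:3, coronal = 1:2, axial = 1:3, lung = 1:2)
  data.frame(
    region_id = seq_len(36),
    lung = c("L", "R")[grid$lung],
    axial_third = c("apical", "middle", "basal")[grid$axial],
    coronal_half = c("anterior", "posterior")[grid$coronal],
    shell = c("peripheral", "middle", "central")[grid$shell],
    voxel_count = cnt,
    absent = cnt == 0,
    stringsAsFactors = FALSE)
}

#' Region table of an atlas
#'
#' One row per atlas region (always 36 rows) with its geometric factors,
#' voxel count, and an `absent` flag for empty regions.
#'
#' @param atlas an `fg_atlas`.
#' @return data.frame with 36 rows.
#' @export
atlas_summary <- function(atlas) {
  stopifnot(inherits(atlas, "fg_atlas"))
  atlas$table
}

#' @exportS3Method base::print
print.fg_atlas <- function(x, ...) {
  cat(sprintf("<fg_atlas> %s voxels, %d/36 regions present\n",
              paste(dim(x$labels), collapse = "x"), sum(!x$table$absent)))
  invisible(x)
}
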