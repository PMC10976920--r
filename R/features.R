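xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' Texture intermediate matrices for one region
#'
#' Computes the five texture-family intermediates from a cropped integer
#' gray-level array (0 outside the region): symmetric GLCM counts over the
#' 13 unique 3D direction pairs at distance 1, GLRLM run counts over the
#' same directions, GLSZM zones (26-connected constant-level components),
#' the NGTDM count/absolute-difference table, and the GLDM dependence
#' matrix with 26-connectivity.
#'
#' @param levels integer 3D array, 0 outside the region, 1..ngray inside.
#' @param ngray number of gray levels.
#' @param gldm_alpha dependence tolerance on |level difference| (default 0).
#' @return list with elements `glcm`, `glrlm`, `glszm_zones`, `ngtdm`,
#'   `gldm`.
#' @export
region_texture_matrices <- function(levels, ngray, gldm_alpha = 0L) {
  stopifnot(length(dim(levels)) == 3, ngray >= 1)
  if (sum(levels > 0) < 2) stop("texture matrices need at least 2 region voxels")
  d <- dim(levels)
  lv <- as.integer(levels)
  list(glcm = cpp_glcm13(lv, d, ngray),
       glrlm = cpp_glrlm13(lv, d, ngray),
       glszm_zones = cpp_glszm_zones(lv, d),
       ngtdm = cpp_ngtdm(lv, d, ngray),
       gldm = cpp_gldm(lv, d, ngray, as.integer(gldm_alpha)))
}

glcm_features_one <- function(p, ng) {
  i <- seq_len(ng)
  px <- rowSums(p)               # symmetric: px == py
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ij <- outer(i, i, "+"); dij <- abs(outer(i, i, "-"))
  psum <- tapply(as.numeric(p), ij, sum)            # k = 2..2Ng
  ks <- as.numeric(names(psum))
  pdiff <- tapply(as.numeric(p), dij, sum)          # k = 0..Ng-1
  kd <- as.numeric(names(pdiff))
  HXY <- -sum(p * xlog2(p))
  pxy <- outer(px, px)
  HXY1 <- -sum(p * xlog2(pxy))
  HXY2 <- -sum(pxy * xlog2(pxy))
  HX <- -sum(px * xlog2(px))
  da <- sum(kd * pdiff)
  autoc <- sum(outer(i, i) * p)
  c(Autocorrelation = autoc,
    ClusterProminence = sum((ij - 2 * mu)^4 * p),
    ClusterShade = sum((ij - 2 * mu)^3 * p),
    ClusterTendency = sum((ij - 2 * mu)^2 * p),
    Contrast = sum((outer(i, i, "-"))^2 * p),
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * xlog2(pdiff)),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(p / (1 + dij)),
    Idm = sum(p / (1 + dij^2)),
    Idmn = sum(p / (1 + dij^2 / ng^2)),
    Idn = sum(p / (1 + dij / ng)),
    Imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    InverseVariance = sum(p[dij > 0] / dij[dij > 0]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    MaximumProbability = max(p),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum * xlog2(psum)),
    SumSquares = sig2)
}

glcm_features <- function(counts) {
  ng <- dim(counts)[1]
  acc <- NULL; nd <- 0
  for (d in seq_len(dim(counts)[3])) {
    C <- matrix(counts[, , d], ng, ng)
    N <- sum(C)
    if (N == 0) next
    f <- glcm_features_one(C / N, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) return(stats::setNames(rep(0, length(FAMILY_FEATURES$glcm)), FAMILY_FEATURES$glcm))
  (acc / nd)[FAMILY_FEATURES$glcm]
}

glrlm_features_one <- function(P, np) {
  ng <- nrow(P); mr <- ncol(P)
  Nr <- sum(P)
  i <- seq_len(ng); j <- seq_len(mr)
  ri <- rowSums(P); rj <- colSums(P)
  p <- P / Nr
  mui <- sum(i * rowSums(p)); muj <- sum(j * colSums(p))
  ii2 <- i^2; jj2 <- j^2
  c(GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    GrayLevelVariance = sum(sweep(p, 1, (i - mui)^2, "*")),
    HighGrayLevelRunEmphasis = sum(ri * ii2) / Nr,
    LongRunEmphasis = sum(rj * jj2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * outer(ii2, jj2)) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * outer(1 / ii2, jj2)) / Nr,
    LowGrayLevelRunEmphasis = sum(ri / ii2) / Nr,
    RunEntropy = -sum(p * xlog2(p)),
    RunLengthNonUniformity = sum(rj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    RunPercentage = Nr / np,
    RunVariance = sum(sweep(p, 2, (j - muj)^2, "*")),
    ShortRunEmphasis = sum(rj / jj2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * outer(ii2, 1 / jj2)) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P * outer(1 / ii2, 1 / jj2)) / Nr)
}

glrlm_features <- function(counts, np) {
  acc <- NULL; nd <- 0
  for (d in seq_len(dim(counts)[3])) {
    P <- counts[, , d, drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, nrow = dim(counts)[1])
    if (sum(P) == 0) next
    f <- glrlm_features_one(P, np)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) return(stats::setNames(rep(0, length(FAMILY_FEATURES$glrlm)), FAMILY_FEATURES$glrlm))
  (acc / nd)[FAMILY_FEATURES$glrlm]
}

glszm_features <- function(zones, np) {
  nz <- nrow(zones)
  nm <- FAMILY_FEATURES$glszm
  if (nz == 0) return(stats::setNames(rep(0, length(nm)), nm))
  lev <- zones[, 1]; size <- zones[, 2]
  ni <- table(lev); ns <- table(size)
  pair <- table(paste(lev, size))
  pp <- as.numeric(pair) / nz
  mu_l <- mean(lev); mu_s <- mean(size)
  out <- c(GrayLevelNonUniformity = sum(as.numeric(ni)^2) / nz,
    GrayLevelVariance = mean((lev - mu_l)^2),
    HighGrayLevelZoneEmphasis = mean(lev^2),
    LargeAreaEmphasis = mean(size^2),
    LargeAreaHighGrayLevelEmphasis = mean(size^2 * lev^2),
    LargeAreaLowGrayLevelEmphasis = mean(size^2 / lev^2),
    LowGrayLevelZoneEmphasis = mean(1 / lev^2),
    SizeZoneNonUniformity = sum(as.numeric(ns)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.numeric(ns)^2) / nz^2,
    SmallAreaEmphasis = mean(1 / size^2),
    SmallAreaHighGrayLevelEmphasis = mean(lev^2 / size^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (lev^2 * size^2)),
    ZoneEntropy = -sum(pp * xlog2(pp)),
    ZonePercentage = nz / np,
    ZoneVariance = mean((size - mu_s)^2))
  out[nm]
}

ngtdm_features <- function(mat) {
  nm <- FAMILY_FEATURES$ngtdm
  n_i <- mat[, 1]; s_i <- mat[, 2]
  N <- sum(n_i)
  present <- which(n_i > 0)
  ngp <- length(present)
  if (N == 0) return(stats::setNames(rep(0, length(nm)), nm))
  p_i <- n_i / N
  iv <- seq_along(n_i)
  denom_co <- sum(p_i * s_i)
  coarseness <- if (denom_co > 0) 1 / denom_co else 1e6
  if (ngp > 1) {
    pi_p <- p_i[present]; ip <- iv[present]; sp <- s_i[present]
    dmat <- abs(outer(ip, ip, "-"))
    contrast <- (sum(outer(pi_p, pi_p) * dmat^2) / (ngp * (ngp - 1))) * (sum(sp) / N)
    den_b <- sum(abs(outer(ip * pi_p, ip * pi_p, "-")))
    busyness <- if (den_b > 0) denom_co / den_b else 0
    num_c <- outer(pi_p * sp, pi_p * sp, "+")
    den_c <- outer(pi_p, pi_p, "+")
    complexity <- sum(dmat * num_c / den_c) / N
    strength <- if (sum(sp) > 0) sum(outer(pi_p, pi_p, "+") * dmat^2) / sum(sp) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
           Contrast = contrast, Strength = strength)
  out[nm]
}

gldm_features <- function(P, np) {
  nm <- FAMILY_FEATURES$gldm
  Nz <- sum(P)
  if (Nz == 0) return(stats::setNames(rep(0, length(nm)), nm))
  ng <- nrow(P); nd <- ncol(P)
  i <- seq_len(ng); j <- seq_len(nd)
  p <- P / Nz
  ri <- rowSums(P); rj <- colSums(P)
  mui <- sum(i * rowSums(p)); muj <- sum(j * colSums(p))
  ii2 <- i^2; jj2 <- j^2
  out <- c(DependenceEntropy = -sum(p * xlog2(p)),
    DependenceNonUniformity = sum(rj^2) / Nz,
    DependenceNonUniformityNormalized = sum(rj^2) / Nz^2,
    DependenceVariance = sum(sweep(p, 2, (j - muj)^2, "*")),
    GrayLevelNonUniformity = sum(ri^2) / Nz,
    GrayLevelVariance = sum(sweep(p, 1, (i - mui)^2, "*")),
    HighGrayLevelEmphasis = sum(ri * ii2) / Nz,
    LargeDependenceEmphasis = sum(rj * jj2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * outer(ii2, jj2)) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * outer(1 / ii2, jj2)) / Nz,
    LowGrayLevelEmphasis = sum(ri / ii2) / Nz,
    SmallDependenceEmphasis = sum(rj / jj2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * outer(ii2, 1 / jj2)) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P * outer(1 / ii2, 1 / jj2)) / Nz)
  out[nm]
}

first_order_features <- function(vals, levels) {
  n <- length(vals)
  m <- mean(vals)
  v <- mean((vals - m)^2)                      # population variance
  q <- quantile(vals, c(0.1, 0.25, 0.75, 0.9), type = 7, names = FALSE)
  mid <- vals[vals >= q[1] & vals <= q[4]]
  hist_p <- tabulate(levels) / n
  sk <- if (v > 0) mean((vals - m)^3) / v^1.5 else 0
  ku <- if (v > 0) mean((vals - m)^4) / v^2 else 0
  c(Energy = sum(vals^2),
    Entropy = -sum(hist_p * xlog2(hist_p)),
    Minimum = min(vals),
    Percentile10 = q[1], Percentile90 = q[4],
    Maximum = max(vals),
    Mean = m, Median = median(vals),
    InterquartileRange = q[3] - q[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - m)),
    RobustMeanAbsoluteDeviation = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = sk, Kurtosis = ku,
    Variance = v,
    Uniformity = sum(hist_p^2))[FAMILY_FEATURES$first_order]
}

shape_features <- function(coords, crop_mask, spacing) {
  nm <- FAMILY_FEATURES$shape
  n <- nrow(coords)
  voxvol <- prod(spacing)
  d <- dim(crop_mask)
  # exposed faces per axis
  area <- 0; nb_boundary <- rep(FALSE, n)
  lin_idx <- (coords[, 3] - 1) * d[1] * d[2] + (coords[, 2] - 1) * d[1] + coords[, 1]
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + s
      outside <- nb[, ax] < 1 | nb[, ax] > d[ax]
      inb <- !outside
      nb_lin <- (nb[inb, 3] - 1) * d[1] * d[2] + (nb[inb, 2] - 1) * d[1] + nb[inb, 1]
      exposed <- outside
      exposed[inb] <- !crop_mask[nb_lin]
      area <- area + sum(exposed) * face_area[ax]
      nb_boundary <- nb_boundary | exposed
    }
  }
  mesh_vol <- max((n - sum(nb_boundary) / 2) * voxvol, voxvol / 2)
  mm <- sweep(coords, 2, c(0.5, 0.5, 0.5)) # centers
  mm <- sweep(mm, 2, spacing, "*")
  if (n > 3) {
    ev <- sort(pmax(eigen(stats::cov(mm), symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  dia <- if (sum(nb_boundary) >= 2)
    cpp_max_diameters(coords[nb_boundary, , drop = FALSE] - 1L, spacing)
  else c(0, 0, 0, 0)
  out <- c(Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    LeastAxisLength = 4 * sqrt(ev[3]),
    MajorAxisLength = 4 * sqrt(ev[1]),
    Maximum2DDiameterColumn = dia[3],   # coronal plane (fixed y)
    Maximum2DDiameterRow = dia[4],      # sagittal plane (fixed x)
    Maximum2DDiameterSlice = dia[2],    # axial plane (fixed z)
    Maximum3DDiameter = dia[1],
    MeshVolume = mesh_vol,
    MinorAxisLength = 4 * sqrt(ev[2]),
    Sphericity = if (area > 0) (36 * pi * mesh_vol^2)^(1 / 3) / area else 0,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / mesh_vol,
    VoxelVolume = n * voxvol)
  out[nm]
}

#' Compute one feature family for one region
#'
#' @param x family intermediates: raw+discretised intensities for
#'   `first_order` (list with `vals`, `levels`), the output of
#'   [region_texture_matrices()] for texture families, or a list with
#'   `coords`, `crop_mask`, `spacing` for `shape`.
#' @param family one of the catalog families.
#' @param n_voxels region voxel count (needed by run/zone/dependence
#'   percentages).
#' @return named numeric vector of the family's features.
#' @export
compute_family_features <- function(x, family, n_voxels = NULL) {
  switch(family,
    first_order = first_order_features(x$vals, x$levels),
    glcm = glcm_features(x$glcm),
    glrlm = glrlm_features(x$glrlm, n_voxels),
    glszm = glszm_features(x$glszm_zones, n_voxels),
    ngtdm = ngtdm_features(x$ngtdm),
    gldm = gldm_features(x$gldm, n_voxels),
    shape = shape_features(x$coords, x$crop_mask, x$spacing),
    stop("unknown family: ", family))
}

#' Extract the per-region feature table of one scan
#'
#' Computes every catalog feature on every atlas region. Texture and
#' first-order families are evaluated per filtered image type; shape
#' features once per region from its geometry. Rows for absent regions (and
#' texture features of regions below 2 voxels) are `NA`.
#'
#' @param volume isotropic `fg_volume`.
#' @param atlas `fg_atlas` congruent with the volume.
#' @param catalog an `fg_catalog` (default full 1004-feature catalog).
#' @param filtered optional precomputed [apply_filters()] output.
#' @return numeric matrix 36 x |catalog| with region ids as rownames; the
#'   catalog is attached as attribute `catalog`.
#' @export
extract_region_features <- function(volume, atlas, catalog = build_catalog(),
                                    filtered = NULL) {
  stopifnot(inherits(volume, "fg_volume"), inherits(atlas, "fg_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("volume and atlas shapes differ")
  present <- which(!atlas$table$absent)
  if (length(present) == 0) stop("no present regions in atlas")
  if (is.null(filtered)) filtered <- apply_filters(volume, catalog$image_types)
  tab <- catalog$table
  out <- matrix(NA_real_, nrow = 36, ncol = nrow(tab),
                dimnames = list(sprintf("r%02d", 1:36), tab$id))
  d <- dim(volume$data)
  spacing <- volume$spacing
  tex_fams <- intersect(catalog$families, c("glcm", "glrlm", "glszm", "ngtdm", "gldm"))
  col_index <- split(seq_len(nrow(tab)), paste(tab$image_type, tab$family))

  for (rid in present) {
    idx <- which(atlas$labels == rid)
    n <- length(idx)
    co <- arrayInd(idx, d)
    lo <- pmax(apply(co, 2, min) - 1L, 1L); hi <- pmin(apply(co, 2, max) + 1L, d)
    cd <- hi - lo + 1L
    co_c <- sweep(co, 2, lo - 1L)
    lin_c <- (co_c[, 3] - 1) * cd[1] * cd[2] + (co_c[, 2] - 1) * cd[1] + co_c[, 1]
    crop_mask <- array(FALSE, cd); crop_mask[lin_c] <- TRUE

    if ("shape" %in% catalog$families) {
      cols <- col_index[["original shape"]]
      if (!is.null(cols))
        out[rid, cols] <- shape_features(co_c, crop_mask, spacing)
    }
    for (it in catalog$image_types) {
      img <- filtered[[it]]
      vals <- img[idx]
      wav <- grepl("^wavelet-", it)
      levels_v <- if (wav) discretize(vals, n_bins = catalog$wavelet_bins)
                  else discretize(vals, bin_width = catalog$bin_width)
      if ("first_order" %in% catalog$families) {
        cols <- col_index[[paste(it, "first_order")]]
        if (!is.null(cols))
          out[rid, cols] <- first_order_features(vals, levels_v)
      }
      if (length(tex_fams) && n >= 2) {
        ngray <- max(levels_v)
        lv <- array(0L, cd); lv[lin_c] <- levels_v
        mats <- region_texture_matrices(lv, ngray)
        for (fam in tex_fams) {
          cols <- col_index[[paste(it, fam)]]
          if (!is.null(cols))
            out[rid, cols] <- compute_family_features(mats, fam, n_voxels = n)
        }
      }
    }
  }
  attr(out, "catalog") <- catalog
  out
}
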