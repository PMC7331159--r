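#' Specification of a synthetic multi-echo acquisition
#'
#' Voxel signal follows a mono-exponential decay
#' `S(TE) = S0 * exp(-TE / T2*)` plus acquisition noise. Default echo times
#' match a multi-echo fast-field-echo protocol at 3 T; the synovial-fluid
#' compartment defaults to a T2* mean above the 50 ms fluid cutoff so the
#' cutoff logic is exercised (fluid T2 is ~100 ms and T2* roughly half of T2).
#'
#' @param echo_times echo times in ms, strictly increasing.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @param tissue_t2star named list with `cartilage` and `fluid`, each
#'   `c(mean, sd)` in ms.
#' @param s0 named list of proton-density signal amplitudes per tissue.
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @param noise_model `"gaussian"` or `"rician"` (magnitude of complex
#'   Gaussian noise).
#' @param fluid_margin thickness of the synovial fluid shell surrounding the
#'   cartilage boundaries, mm.
#' @param seed integer substream seed.
#' @return object of class `EchoSpec`.
#' @export
echo_spec <- function(echo_times = c(3.83, 9.37, 14.91, 20.46, 26.01),
                      voxel_size = c(0.3, 0.3, 0.3),
                      tissue_t2star = list(cartilage = c(25, 3), fluid = c(55, 2)),
                      s0 = list(cartilage = 800, fluid = 1000),
                      noise_sd = 15, noise_model = c("gaussian", "rician"),
                      fluid_margin = 0.5, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(echo_times) >= 1, all(echo_times > 0),
            all(diff(echo_times) > 0), noise_sd >= 0)
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  structure(list(echo_times = echo_times, voxel_size = voxel_size,
                 tissue_t2star = tissue_t2star, s0 = s0, noise_sd = noise_sd,
                 noise_model = noise_model, fluid_margin = fluid_margin,
                 seed = as.integer(seed)),
            class = "EchoSpec")
}

#' Generate a synthetic multi-echo volume of a posed shoulder
#'
#' Voxels are labeled analytically from the generator's spherical geometry
#' (not from the meshes): cartilage where the voxel center lies inside either
#' cartilage layer, synovial fluid in a shell of `fluid_margin` around the
#' articulating surfaces, background elsewhere. Each tissue voxel draws its
#' ground-truth T2* from the tissue distribution; `t2star_offset_fn` can add
#' a spatial offset to cartilage T2* (used to couple T2* change to strain
#' change in end-to-end studies).
#'
#' @param spec an [echo_spec()].
#' @param shoulder a [make_shoulder()] model.
#' @param pose relative humerus-in-glenoid `RigidPose` (default neutral).
#' @param t2star_offset_fn optional `function(xyz_matrix) -> ms` offset added
#'   to cartilage ground-truth T2*.
#' @param margin_mm padding of the bounding box around the glenoid cap, mm.
#' @return object of class `EchoVolume`: `data` (4-D array x,y,z,echo),
#'   `echo_times`, `voxel_size`, `origin`, `labels` (0 background, 1
#'   cartilage, 2 fluid), `t2star_truth`, `spec`.
#' @export
make_multiecho_volume <- function(spec, shoulder, pose = rigid_pose(),
                                  t2star_offset_fn = NULL, margin_mm = 2) {
  stopifnot(inherits(spec, "EchoSpec"), inherits(shoulder, "ShoulderModel"))
  g <- shoulder$geometry
  r_h <- g$head_radius
  amax <- deg2rad(g$cap_half_angle_glenoid + 10)
  rmax <- r_h + 3
  half_xy <- rmax * sin(amax) + margin_mm
  z_lo <- (r_h - 2) * cos(deg2rad(g$cap_half_angle_glenoid + 15))
  z_hi <- rmax + margin_mm
  vs <- spec$voxel_size
  xs <- seq(-half_xy, half_xy, by = vs[1])
  ys <- seq(-half_xy, half_xy, by = vs[2])
  zs <- seq(z_lo, z_hi, by = vs[3])
  dims <- c(length(xs), length(ys), length(zs))
  ctr <- as.matrix(expand.grid(x = xs, y = ys, z = zs))

  # humerus-frame coordinates of voxel centers (humeral layer moves with pose)
  inv <- invert_pose(pose)
  ctr_h <- apply_pose(inv, ctr)
  lab_of <- function(p, art_only = FALSE) {
    r <- sqrt(rowSums(p^2))
    theta <- acos(pmin(1, pmax(-1, p[, 3] / pmax(r, 1e-12))))
    phi <- atan2(p[, 2], p[, 1])
    list(r = r, theta = theta, phi = phi)
  }
  sh <- lab_of(ctr_h)
  sg <- lab_of(ctr)
  t_h <- shoulder$thickness_fn$humeral(sh$theta, sh$phi)
  art_h <- r_h + t_h
  art_g <- g$articular_radius_fn(sg$theta, sg$phi)
  t_g <- shoulder$thickness_fn$scapular(sg$theta, sg$phi)
  in_h_cap <- sh$theta <= deg2rad(g$cap_half_angle_humeral)
  in_g_cap <- sg$theta <= deg2rad(g$cap_half_angle_glenoid)
  hum_cart <- in_h_cap & sh$r >= r_h & sh$r <= art_h
  sca_cart <- in_g_cap & sg$r >= art_g & sg$r <= art_g + t_g
  fm <- spec$fluid_margin
  fluid <- (!hum_cart & !sca_cart) &
    ((in_h_cap & sh$r > art_h & sh$r <= art_h + fm) |
       (in_g_cap & sg$r < art_g & sg$r >= art_g - fm))
  labels <- integer(nrow(ctr))
  labels[fluid] <- 2L
  labels[hum_cart | sca_cart] <- 1L

  tt <- spec$tissue_t2star
  nvox <- nrow(ctr)
  t2 <- rep(NA_real_, nvox)
  s0 <- numeric(nvox)
  sub <- substream_seed(spec$seed, "tissue_t2star")
  t2 <- with_seed(sub, {
    v <- rep(NA_real_, nvox)
    ncart <- sum(labels == 1L); nflu <- sum(labels == 2L)
    v[labels == 1L] <- rnorm(ncart, tt$cartilage[1], tt$cartilage[2])
    v[labels == 2L] <- rnorm(nflu, tt$fluid[1], tt$fluid[2])
    v
  })
  if (!is.null(t2star_offset_fn)) {
    sel <- labels == 1L
    t2[sel] <- t2[sel] + t2star_offset_fn(ctr[sel, , drop = FALSE])
  }
  t2 <- pmax(t2, 1)  # keep relaxation physical
  s0[labels == 1L] <- spec$s0$cartilage
  s0[labels == 2L] <- spec$s0$fluid

  ne <- length(spec$echo_times)
  sig <- outer(ifelse(is.na(t2), 0, 1 / t2), spec$echo_times,
               function(invt2, te) exp(-te * invt2))
  sig <- sig * s0
  if (spec$noise_sd > 0) {
    sig <- with_seed(substream_seed(spec$seed, "acquisition_noise"), {
      if (spec$noise_model == "rician") {
        re <- sig + matrix(rnorm(nvox * ne, sd = spec$noise_sd), nvox, ne)
        im <- matrix(rnorm(nvox * ne, sd = spec$noise_sd), nvox, ne)
        sqrt(re^2 + im^2)
      } else {
        sig + matrix(rnorm(nvox * ne, sd = spec$noise_sd), nvox, ne)
      }
    })
  }
  structure(list(data = array(sig, c(dims, ne)),
                 echo_times = spec$echo_times, voxel_size = vs,
                 origin = c(xs[1], ys[1], zs[1]),
                 labels = array(labels, dims),
                 t2star_truth = array(t2, dims),
                 spec = spec),
            class = "EchoVolume")
}

#' @export
print.EchoVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EchoVolume: %d x %d x %d voxels, %d echoes (TE %s ms)\n",
              d[1], d[2], d[3], d[4],
              paste(x$echo_times, collapse = "/")))
  invisible(x)
}

#' Write an EchoVolume as NIfTI + JSON sidecar
#' @param volume `EchoVolume`.
#' @param path output `.nii` path (sidecar gets the same stem + `.json`).
#' @return `path`, invisibly.
#' @export
write_echo_volume <- function(volume, path) {
  write_nifti(volume$data, path, voxel_size = volume$voxel_size,
              origin = volume$origin)
  write_echo_sidecar(volume$echo_times, sub("\\.nii$", ".json", path))
  invisible(path)
}

#' Read an EchoVolume from NIfTI + JSON sidecar
#' @param path `.nii` path written by [write_echo_volume()].
#' @return `EchoVolume` (without ground-truth labels).
#' @export
read_echo_volume <- function(path) {
  n <- read_nifti(path)
  te <- read_echo_sidecar(sub("\\.nii$", ".json", path))
  if (dim(n$data)[4] != length(te))
    stop("echo count mismatch between volume and sidecar")
  structure(list(data = n$data, echo_times = te, voxel_size = n$voxel_size,
                 origin = n$origin, labels = NULL, t2star_truth = NULL,
                 spec = NULL),
            class = "EchoVolume")
}
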