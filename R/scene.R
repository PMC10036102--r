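# Scene material codes (fixed across the package)
.scene_codes <- c(air = 1L, concrete = 2L, water = 3L, skin = 4L, bone = 5L,
                  eye_lens = 6L, table_top = 7L, shield = 8L)

#' Shield specification
#'
#' The freestanding perforated protective board: a vertical panel of 1 mm lead
#' (or 1 mm lead-equivalent acrylic) with rectangular work apertures on the
#' echocardiographer (left, +y) and anesthesiologist (right, -y) sides.
#' Aperture height bands from the floor: pattern `"large"` 100-140 cm on the
#' echo side and 90-130 cm on the anesthetic side; `"small"` 105-125 cm and
#' 95-115 cm; `"none_aperture"` is a solid panel; `"absent"` produces no
#' shield at all. Aperture widths default to 35 cm (large) and 25 cm (small)
#' per side, centred on each worker's station.
#'
#' @param pattern One of `"absent"`, `"large"`, `"small"`, `"none_aperture"`.
#' @param thickness_mm Panel thickness in mm of `material`.
#' @param material Shield material registry name.
#' @param width_m,height_m Panel width and height (m).
#' @param floor_offset_m Height of the lower panel edge above the floor.
#' @param standoff_m Distance from the patient's head plane to the panel.
#' @param aperture Optional list overriding the per-side apertures; each side
#'   (`echo`, `anes`) is `list(band_cm = c(lo, hi), width_cm, offset_cm)`.
#' @return An object of class `fs_shield_spec`.
#' @export
#' @examples
#' shield_spec("small")
shield_spec <- function(pattern = c("absent", "large", "small", "none_aperture"),
                        thickness_mm = 1, material = "lead",
                        width_m = 1.0, height_m = 1.8, floor_offset_m = 0,
                        standoff_m = 0.30, aperture = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(aperture)) {
    aperture <- switch(pattern,
      absent = list(),
      none_aperture = list(),
      large = list(echo = list(band_cm = c(100, 140), width_cm = 35, offset_cm = 25),
                   anes = list(band_cm = c(90, 130), width_cm = 35, offset_cm = -25)),
      small = list(echo = list(band_cm = c(105, 125), width_cm = 25, offset_cm = 25),
                   anes = list(band_cm = c(95, 115), width_cm = 25, offset_cm = -25)))
  }
  if (pattern %in% c("absent", "none_aperture") && length(aperture) > 0)
    abort(paste0("pattern '", pattern, "' admits no apertures"))
  for (ap in aperture) {
    if (ap$band_cm[1] < floor_offset_m * 100 ||
        ap$band_cm[2] > (floor_offset_m + height_m) * 100 ||
        abs(ap$offset_cm) + ap$width_cm / 2 > width_m * 100 / 2)
      abort("aperture lies outside the shield panel")
  }
  structure(list(pattern = pattern, thickness_mm = thickness_mm,
                 material = material, width_m = width_m, height_m = height_m,
                 floor_offset_m = floor_offset_m, standoff_m = standoff_m,
                 aperture = aperture),
            class = "fs_shield_spec")
}

#' Operating-room scene configuration
#'
#' Describes the room, table, undertable x-ray source, patient and staff
#' phantoms and shield. All lengths in metres unless suffixed `_cm`; z = 0 at
#' the floor, z up, right-handed axes with the patient lying along +x (head
#' towards the shield and the anesthesiologist).
#'
#' @param room Interior room size `c(x, y, z)` in m.
#' @param wall_m Concrete wall/floor/ceiling thickness (m).
#' @param table_height_m,table_thickness_m,table_width_m,table_length_m
#'   Imaging-table geometry; the tabletop is a low-density water-equivalent
#'   (carbon-fibre-like) slab.
#' @param table_density Effective tabletop density in g/cm^3.
#' @param ssd_m Source-to-surface distance at the PA direction.
#' @param sid_m Source-to-image-receptor distance; must exceed `ssd_m`.
#' @param field_mm Side of the square collimated field at the receptor plane.
#' @param projection A name (`"PA"`, `"cusp_overlap"`, `"perpendicular"`) or
#'   `list(rao_lao = deg, cra_cau = deg)` (RAO and CRA positive).
#' @param shield A [shield_spec()].
#' @param patient `list(height_cm =, on = TRUE)` for the supine stylized
#'   patient phantom.
#' @param staff `list(height_cm =, stance_deg =, on = TRUE)` for the standing
#'   staff (anesthesiologist) phantom; stance is measured from the patient
#'   axis.
#' @return An object of class `fs_scene_config`.
#' @export
#' @examples
#' cfg <- scene_config(shield = shield_spec("small"))
scene_config <- function(room = c(8.1, 7.3, 3.4), wall_m = 0.20,
                         table_height_m = 1.00, table_thickness_m = 0.02,
                         table_width_m = 0.50, table_length_m = 2.20,
                         table_density = 0.55,
                         ssd_m = 0.60, sid_m = 1.00, field_mm = 156.5,
                         projection = "PA",
                         shield = shield_spec("absent"),
                         patient = list(height_cm = 170, on = TRUE),
                         staff = list(height_cm = 160.8, stance_deg = 45,
                                      on = TRUE)) {
  if (ssd_m >= sid_m) abort("SSD must be smaller than SID")
  if (field_mm <= 0) abort("field side must be > 0")
  stopifnot(length(room) == 3, all(room > 0))
  cfg <- structure(list(
    room = room, wall_m = wall_m,
    table = list(height_m = table_height_m, thickness_m = table_thickness_m,
                 width_m = table_width_m, length_m = table_length_m,
                 density = table_density),
    source = list(ssd_m = ssd_m, sid_m = sid_m, field_mm = field_mm),
    projection = projection, shield = shield,
    patient = utils::modifyList(list(height_cm = 170, on = TRUE), patient),
    staff = utils::modifyList(list(height_cm = 160.8, stance_deg = 45,
                                   on = TRUE), staff)),
    class = "fs_scene_config")
  layout <- scene_layout(cfg)
  if (layout$staff_x + 0.3 > room[1] || layout$shield_x > room[1])
    abort("room too small to contain table, phantoms and shield")
  cfg
}

# derived anchor points of the scene (m)
scene_layout <- function(cfg) {
  cx <- cfg$room[1] / 2; cy <- cfg$room[2] / 2
  z_support <- cfg$table$height_m              # patient posterior surface
  trunk_b <- 0.11                              # patient trunk half thickness
  head_x <- cx + 0.55                          # top of the patient's head
  list(cx = cx, cy = cy, z_support = z_support,
       iso = c(cx, cy, z_support + trunk_b),
       iso_depth = trunk_b,
       head_x = head_x,
       table_x_max = head_x + 0.05,            # table ends just past the head
       shield_x = head_x + cfg$shield$standoff_m,
       staff_x = head_x + 0.95, staff_y = cy - 0.15)
}

#' Set the beam projection of a scene configuration
#'
#' @param config An `fs_scene_config`.
#' @param projection `"PA"`, `"cusp_overlap"` (RAO 9, CAU 1),
#'   `"perpendicular"` (LAO 16, CRA 13), or `list(rao_lao =, cra_cau =)` in
#'   signed degrees (RAO and CRA positive).
#' @return The updated configuration.
#' @export
set_projection <- function(config, projection) {
  config$projection <- projection
  projection_geometry(config)   # validates
  config
}

projection_angles <- function(projection) {
  if (is.character(projection)) {
    ang <- switch(projection,
                  PA = c(0, 0), cusp_overlap = c(9, -1),
                  perpendicular = c(-16, 13),
                  abort(paste0("unknown projection '", projection,
                               "'; use PA, cusp_overlap, perpendicular")))
  } else {
    ang <- c(projection$rao_lao, projection$cra_cau)
  }
  if (any(abs(ang) > 45)) abort("unsupported angulation: |angle| > 45 degrees")
  ang
}

rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Source geometry for a configured projection
#'
#' The central axis starts from +z (PA, undertable tube facing straight up)
#' and is rotated first by the RAO/LAO angle about the patient's longitudinal
#' axis (x, RAO tilts the receptor towards the patient's right, -y), then by
#' the CRA/CAU angle about the lateral axis (y, CRA towards the head, +x).
#' The point source sits on the rotated axis at the source-to-isocenter
#' distance `ssd + iso_depth` below the isocenter.
#'
#' @param config An `fs_scene_config`.
#' @return A list: `source_pos`, `axis` (unit vector), `u`, `v` (field basis),
#'   `half_x_m`, `half_y_m` (field half-sides at the receptor), `sid_m`,
#'   `iso`, `angles_deg`.
#' @export
projection_geometry <- function(config) {
  ang <- projection_angles(config$projection)
  lay <- scene_layout(config)
  axis <- as.vector(rot_y(ang[2]) %*% rot_x(ang[1]) %*% c(0, 0, 1))
  d_si <- config$source$ssd_m + lay$iso_depth
  src <- lay$iso - d_si * axis
  u <- c(axis[3], 0, -axis[1]); nu <- sqrt(sum(u^2))
  if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  half <- config$source$field_mm / 2000
  list(source_pos = src, axis = axis, u = u, v = v,
       half_x_m = half, half_y_m = half, sid_m = config$source$sid_m,
       iso = lay$iso, angles_deg = c(rao_lao = ang[1], cra_cau = ang[2]))
}

# ---- stylized phantoms -------------------------------------------------------

# body segments as fractions of total height: z ranges and elliptical
# half-axes (lateral, anteroposterior), m per 1.7 m reference scaled linearly
.body_segments <- function(height_m) {
  s <- height_m / 1.70
  list(
    legs  = list(frac = c(0.00, 0.470), a_lat = 0.17 * s, a_ap = 0.120 * s),
    trunk = list(frac = c(0.470, 0.780), a_lat = 0.17 * s, a_ap = 0.110 * s),
    neck  = list(frac = c(0.780, 0.835), a_lat = 0.055 * s, a_ap = 0.055 * s),
    head  = list(frac = c(0.835, 1.000), a_lat = 0.080 * s, a_ap = 0.100 * s))
}

# material codes for a standing phantom, vectorized over points (m).
# axial = height above the feet; lat/ap = local lateral / anterior offsets.
phantom_code_local <- function(axial, lat, ap, height_m, shell_m,
                               lens = FALSE) {
  code <- integer(length(axial))
  segs <- .body_segments(height_m)
  for (nm in names(segs)) {
    sg <- segs[[nm]]
    zr <- sg$frac * height_m
    in_z <- axial >= zr[1] & axial < zr[2]
    if (!any(in_z)) next
    r <- sqrt((lat / sg$a_lat)^2 + (ap / sg$a_ap)^2)
    t_sh <- shell_m / min(sg$a_lat, sg$a_ap)
    inside <- in_z & r <= 1
    code[inside & r <= 0.35] <- .scene_codes[["bone"]]
    code[inside & r > 0.35 & r < 1 - t_sh] <- .scene_codes[["water"]]
    skin <- inside & r >= 1 - t_sh
    code[skin] <- .scene_codes[["skin"]]
    if (lens && nm == "head") {
      lb <- c(0.902, 0.933) * height_m    # 145-150 cm at the 160.8 cm default
      patch <- skin & axial >= lb[1] & axial < lb[2] &
        ap > 0 & abs(lat) >= 0.01 & abs(lat) <= 0.05
      code[patch] <- .scene_codes[["eye_lens"]]
    }
  }
  code
}

# standing staff phantom: x,y,z world coords; anchor at (px, py) on the floor,
# stance in degrees from the patient (+x) axis.
staff_code_at <- function(x, y, z, px, py, stance_deg, height_m, shell_m) {
  th <- stance_deg * pi / 180
  ant <- c(-cos(th), sin(th))          # anterior (facing) direction
  rgt <- c(ant[2], -ant[1])            # subject's right = anterior x z-up
  dx <- x - px; dy <- y - py
  ap <- dx * ant[1] + dy * ant[2]
  lat <- dx * rgt[1] + dy * rgt[2]
  phantom_code_local(z, lat, ap, height_m, shell_m, lens = TRUE)
}

# supine patient along +x, head at head_x, posterior surface at z0
patient_code_at <- function(x, y, z, head_x, cy, z0, height_m, shell_m) {
  axial <- height_m - (head_x - x)     # distance from the feet
  segs <- .body_segments(height_m)
  code <- integer(length(x))
  for (nm in names(segs)) {
    sg <- segs[[nm]]
    zr <- sg$frac * height_m
    in_a <- axial >= zr[1] & axial < zr[2]
    if (!any(in_a)) next
    r <- sqrt(((y - cy) / sg$a_lat)^2 + ((z - z0 - sg$a_ap) / sg$a_ap)^2)
    t_sh <- shell_m / min(sg$a_lat, sg$a_ap)
    inside <- in_a & r <= 1
    code[inside & r <= 0.35] <- .scene_codes[["bone"]]
    code[inside & r > 0.35 & r < 1 - t_sh] <- .scene_codes[["water"]]
    code[inside & r >= 1 - t_sh] <- .scene_codes[["skin"]]
  }
  code
}

# ---- voxelization ------------------------------------------------------------

voxel_centers <- function(origin, spacing, n) origin + (seq_len(n) - 0.5) * spacing

#' Build a voxelized operating-room scene
#'
#' Fills a regular grid (half-open voxels, material decided at the voxel
#' centre) with air, concrete walls/floor/ceiling, the tabletop, the supine
#' patient, the standing staff phantom and the shield. Overlaps resolve by the
#' priority shield > staff > patient > table > walls > air. A shield panel
#' thinner than one voxel is homogenized: the voxel layer is assigned the
#' shield material with density scaled so the areal density (and hence the
#' transmission along any chord) is preserved.
#'
#' @param config An `fs_scene_config`.
#' @param spacing_m Voxel edge length (m); the same in all axes.
#' @return An `fs_voxel_scene`: origin/spacing/dims, an integer material index
#'   array, a material table (label, base registry material, density used), a
#'   named list of ROI voxel indices on the staff phantom, and metadata.
#' @export
#' @examples
#' sc <- build_room_scene(scene_config(room = c(3, 3, 3),
#'                                     patient = list(on = FALSE),
#'                                     staff = list(on = FALSE)), 0.10)
#' dim(sc$index)
build_room_scene <- function(config, spacing_m = 0.05) {
  lay <- scene_layout(config)
  w <- config$wall_m
  origin <- c(-w, -w, -w)
  ext <- config$room + 2 * w
  dims <- pmax(as.integer(round(ext / spacing_m)), 1L)
  xs <- voxel_centers(origin[1], spacing_m, dims[1])
  ys <- voxel_centers(origin[2], spacing_m, dims[2])
  shell <- max(spacing_m, 0.002)

  sh <- config$shield
  shield_on <- sh$pattern != "absent"
  rho_shield <- NA_real_
  if (shield_on) {
    mat <- get_material(sh$material)
    t_m <- sh$thickness_mm / 1000
    rho_shield <- mat$density * min(1, t_m / spacing_m)
  }

  idx <- array(.scene_codes[["air"]], dim = dims)
  roi_acc <- list()
  xy <- expand.grid(x = xs, y = ys)   # slice-wise fill
  gx <- xy$x; gy <- xy$y
  in_room_xy <- gx >= 0 & gx <= config$room[1] & gy >= 0 & gy <= config$room[2]
  tb <- config$table
  in_table_xy <- gx <= lay$table_x_max & gx >= lay$table_x_max - tb$length_m &
    abs(gy - lay$cy) <= tb$width_m / 2
  shield_col <- if (shield_on) {
    ix_sh <- which.max(xs > lay$shield_x)   # first voxel column past the plane
    if (xs[ix_sh] <= lay$shield_x) ix_sh <- dims[1]
    ix_sh
  } else 0L

  for (k in seq_len(dims[3])) {
    z <- origin[3] + (k - 0.5) * spacing_m
    slab <- rep(.scene_codes[["air"]], length(gx))
    outside <- !in_room_xy | z < 0 | z > config$room[3]
    slab[outside] <- .scene_codes[["concrete"]]
    # tabletop: overlap of this voxel layer with the slab [h - th, h)
    overlap <- min(z + spacing_m / 2, tb$height_m) -
      max(z - spacing_m / 2, tb$height_m - tb$thickness_m)
    if (overlap > spacing_m / 2 ||
        (overlap > 0 && tb$thickness_m < spacing_m &&
         z + spacing_m / 2 >= tb$height_m - tb$thickness_m / 2 &&
         z - spacing_m / 2 < tb$height_m - tb$thickness_m / 2))
      slab[in_table_xy & !outside] <- .scene_codes[["table_top"]]
    if (isTRUE(config$patient$on)) {
      pc <- patient_code_at(gx, gy, rep(z, length(gx)), lay$head_x, lay$cy,
                            tb$height_m, config$patient$height_cm / 100, shell)
      slab[pc > 0 & !outside] <- pc[pc > 0 & !outside]
    }
    if (isTRUE(config$staff$on)) {
      scd <- staff_code_at(gx, gy, rep(z, length(gx)), lay$staff_x, lay$staff_y,
                           config$staff$stance_deg,
                           config$staff$height_cm / 100, shell)
      sel <- scd > 0 & !outside
      slab[sel] <- scd[sel]
    }
    idx[, , k] <- slab
  }

  if (shield_on) {
    zk <- voxel_centers(origin[3], spacing_m, dims[3])
    panel_z <- which(zk >= sh$floor_offset_m & zk < sh$floor_offset_m + sh$height_m)
    panel_y <- which(abs(ys - lay$cy) <= sh$width_m / 2)
    for (k in panel_z) {
      zc <- zk[k]
      row <- idx[shield_col, panel_y, k]
      open <- rep(FALSE, length(panel_y))
      for (ap in sh$aperture) {
        yc <- lay$cy + ap$offset_cm / 100
        in_y <- abs(ys[panel_y] - yc) <= ap$width_cm / 200
        in_z <- zc >= ap$band_cm[1] / 100 & zc < ap$band_cm[2] / 100
        if (in_z) open <- open | in_y
      }
      row[!open] <- .scene_codes[["shield"]]
      idx[shield_col, panel_y, k] <- row
    }
  }

  materials <- tibble(
    code = unname(.scene_codes),
    label = names(.scene_codes),
    base = c("air", "concrete", "water", "skin", "bone", "eye_lens",
             "water", if (shield_on) sh$material else "lead"),
    density = c(get_material("air")$density, get_material("concrete")$density,
                1.0, get_material("skin")$density, get_material("bone")$density,
                get_material("eye_lens")$density,
                config$table$density *
                  min(1, config$table$thickness_m / spacing_m),
                if (shield_on) rho_shield else get_material("lead")$density))

  scene <- structure(list(
    origin = origin, spacing = spacing_m, dims = dims, index = idx,
    materials = materials, roi = list(),
    meta = list(config = config, layout = lay,
                shield_x = if (shield_on) xs[shield_col] else NA_real_,
                spacing_m = spacing_m)),
    class = "fs_voxel_scene")
  if (isTRUE(config$staff$on)) scene$roi <- staff_rois(scene)
  scene
}

# ROI bands (cm from the floor at the 160.8 cm reference, scaled linearly
# with staff height): eye lens 145-150, neck/thyroid 130-135, chest 110-130,
# waist/ovary 80-85. Surface = skin/lens voxels of the staff phantom;
# left/right split by the subject's own sides.
.roi_bands_ref <- list(lens = c(145, 150), neck = c(130, 135),
                       chest = c(110, 130), waist = c(80, 85))

staff_rois <- function(scene) {
  cfg <- scene$meta$config
  lay <- scene$meta$layout
  h <- cfg$staff$height_cm / 100
  sc <- h / 1.608
  dims <- scene$dims
  xs <- voxel_centers(scene$origin[1], scene$spacing, dims[1])
  ys <- voxel_centers(scene$origin[2], scene$spacing, dims[2])
  zs <- voxel_centers(scene$origin[3], scene$spacing, dims[3])
  idx <- scene$index
  surf <- which(idx == .scene_codes[["skin"]] | idx == .scene_codes[["eye_lens"]])
  ai <- arrayInd(surf, dims)
  px <- xs[ai[, 1]]; py <- ys[ai[, 2]]; pz <- zs[ai[, 3]]
  # restrict to the staff phantom (the patient lies below ~1.25 m and far in x)
  th <- cfg$staff$stance_deg * pi / 180
  ant <- c(-cos(th), sin(th)); rgt <- c(ant[2], -ant[1])
  dx <- px - lay$staff_x; dy <- py - lay$staff_y
  on_staff <- sqrt(dx^2 + dy^2) <= 0.30
  lat <- dx * rgt[1] + dy * rgt[2]
  ap <- dx * ant[1] + dy * ant[2]
  facing <- ap > 0
  rois <- list()
  for (nm in names(.roi_bands_ref)) {
    band <- .roi_bands_ref[[nm]] / 100 * sc
    in_band <- on_staff & pz >= band[1] & pz < band[2]
    if (nm %in% c("lens", "chest")) {
      sel_l <- in_band & facing & lat < 0
      sel_r <- in_band & facing & lat >= 0
      if (nm == "lens") {
        is_lens <- idx[surf] == .scene_codes[["eye_lens"]]
        sel_l <- sel_l & is_lens; sel_r <- sel_r & is_lens
        # fall back to the facing skin patch when the grid is too coarse to
        # carve explicit lens voxels
        if (!any(sel_l) || !any(sel_r)) {
          sel_l <- in_band & facing & lat < 0
          sel_r <- in_band & facing & lat >= 0
        }
      }
      rois[[paste0(nm, "_left")]] <- surf[sel_l]
      rois[[paste0(nm, "_right")]] <- surf[sel_r]
    } else {
      rois[[nm]] <- surf[in_band & facing]
    }
  }
  rois
}

#' Voxelize the standing staff phantom alone
#'
#' @param height_cm Total height in cm (140-200).
#' @param stance_deg Stance angle from the patient axis (degrees).
#' @param spacing_m Voxel size (m).
#' @return A list with the material-code array (`index`), `origin`, `spacing`,
#'   total soft-tissue-and-bone `mass_kg`, occupied `volume_m3`, and the ROI
#'   height bands (`bands_cm`).
#' @export
#' @examples
#' ph <- build_staff_phantom(160.8, 45, 0.02)
#' ph$volume_m3
build_staff_phantom <- function(height_cm, stance_deg = 45, spacing_m = 0.01) {
  if (height_cm < 140 || height_cm > 200)
    abort("staff height must lie in [140, 200] cm")
  h <- height_cm / 100
  half <- 0.30
  origin <- c(-half, -half, 0)
  dims <- c(rep(ceiling(2 * half / spacing_m), 2), ceiling(h / spacing_m))
  xs <- voxel_centers(origin[1], spacing_m, dims[1])
  ys <- voxel_centers(origin[2], spacing_m, dims[2])
  idx <- array(0L, dim = dims)
  xy <- expand.grid(x = xs, y = ys)
  shell <- max(spacing_m, 0.002)
  for (k in seq_len(dims[3])) {
    z <- origin[3] + (k - 0.5) * spacing_m
    idx[, , k] <- staff_code_at(xy$x, xy$y, rep(z, nrow(xy)), 0, 0,
                                stance_deg, h, shell)
  }
  vol <- spacing_m^3
  dens <- c(0, 0, 1.0, get_material("skin")$density,
            get_material("bone")$density, get_material("eye_lens")$density)
  counts <- tabulate(idx, nbins = 6)
  mass <- sum(counts * dens) * vol * 1000       # g/cm^3 * m^3 -> kg
  bands <- lapply(.roi_bands_ref, function(b) b * height_cm / 160.8)
  list(index = idx, origin = origin, spacing = spacing_m,
       mass_kg = mass, volume_m3 = sum(idx > 0) * vol, bands_cm = bands,
       height_cm = height_cm, stance_deg = stance_deg)
}

#' Voxelize a shield specification alone
#'
#' @param spec An [shield_spec()].
#' @param spacing_m Voxel size (m).
#' @return A list with the logical occupancy array over the panel bounding box
#'   (`occupied`), per-side aperture voxel counts, and the effective
#'   homogenized density.
#' @export
#' @examples
#' b <- build_shield(shield_spec("large"), 0.05)
#' b$aperture_voxels
build_shield <- function(spec, spacing_m = 0.05) {
  if (spec$pattern == "absent") {
    return(list(occupied = array(FALSE, c(0, 0, 0)),
                aperture_voxels = c(echo = 0L, anes = 0L),
                density = NA_real_))
  }
  ny <- ceiling(spec$width_m / spacing_m)
  nz <- ceiling(spec$height_m / spacing_m)
  ys <- (seq_len(ny) - 0.5) * spacing_m - spec$width_m / 2
  zs <- spec$floor_offset_m + (seq_len(nz) - 0.5) * spacing_m
  occ <- matrix(TRUE, ny, nz)
  ap_count <- c(echo = 0L, anes = 0L)
  for (side in names(spec$aperture)) {
    ap <- spec$aperture[[side]]
    iy <- abs(ys - ap$offset_cm / 100) <= ap$width_cm / 200
    iz <- zs >= ap$band_cm[1] / 100 & zs < ap$band_cm[2] / 100
    occ[iy, iz] <- FALSE
    ap_count[side] <- sum(iy) * sum(iz)
  }
  rho <- get_material(spec$material)$density *
    min(1, spec$thickness_mm / 1000 / spacing_m)
  list(occupied = array(occ, c(1, ny, nz)), aperture_voxels = ap_count,
       density = rho)
}

#' @export
print.fs_voxel_scene <- function(x, ...) {
  cat("<fs_voxel_scene>", paste(x$dims, collapse = " x "), "voxels @",
      x$spacing, "m\n")
  tab <- table(factor(x$index, levels = x$materials$code,
                      labels = x$materials$label))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  if (length(x$roi))
    cat("  ROIs:", paste(sprintf("%s(%d)", names(x$roi),
                                 lengths(x$roi)), collapse = " "), "\n")
  invisible(x)
}

#' Total mass of each material in a scene (kg)
#' @param scene An `fs_voxel_scene`.
#' @return A tibble with `label` and `mass_kg`.
#' @export
scene_mass <- function(scene) {
  counts <- tabulate(scene$index, nbins = max(scene$materials$code))
  tibble(label = scene$materials$label,
         mass_kg = counts[scene$materials$code] * scene$materials$density *
           scene$spacing^3 * 1000)
}
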