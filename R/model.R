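# Planar (sagittal) musculoskeletal model definition.
#
# Reduced skeleton: 10 segments (pelvis, torso, two thighs, shanks, hindfeet,
# forefeet), 12 coordinates (pelvis x/y/tilt, lumbar, hip, knee, ankle and
# midtarsal per side), 9 muscles per leg plus a lumbar flexor/extensor pair,
# 3 Hunt-Crossley contact spheres per foot, and double-exponential passive
# torques with damping on every rotational joint. Muscle paths use constant
# (anatomical-position) moment arms, so musculotendon length is affine in the
# coordinates. Coordinates are radians internally; sign conventions: pelvis
# tilt positive anterior, hip/knee flexion positive, ankle and midtarsal
# dorsiflexion positive; ground is y = 0 with gravity -9.81 m/s^2.

COORD_NAMES <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt", "lumbar",
                 "hip_r", "hip_l", "knee_r", "knee_l",
                 "ankle_r", "ankle_l", "mt_r", "mt_l")
SEGMENT_NAMES <- c("pelvis", "torso", "thigh_r", "shank_r", "hindfoot_r",
                   "forefoot_r", "thigh_l", "shank_l", "hindfoot_l",
                   "forefoot_l")
LEG_MUSCLES <- c("glut_max", "iliopsoas", "hamstrings", "rectus_fem",
                 "vasti", "gastroc", "soleus", "tib_ant", "foot_intrinsic")
TRUNK_MUSCLES <- c("back_ext", "abdominal")

#' Generic model anthropometry
#'
#' Stature and body mass of the unscaled generic adult model; also the basis
#' of the allometric TD mass expectation used by the cohort module.
#' @return list with `height_m` and `mass_kg`
#' @export
generic_anthropometry <- function() list(height_m = 1.75, mass_kg = 75.3)

#' Construct the generic planar musculoskeletal model
#'
#' Builds the package's default reduced sagittal-plane model of an adult of
#' 1.75 m / 75.3 kg. All parameters (segment masses and inertias, muscle
#' maximal forces, optimal fiber and tendon slack lengths, constant moment
#' arms, contact-sphere placement and stiffness, passive joint-torque
#' coefficients) are package constants documented in the model tables;
#' passive-torque coefficients are reconstructions of the usual exponential
#' stiffness-plus-damping family, not fitted values.
#'
#' @return object of class `planar_model`
#' @export
default_planar_model <- function() {
  ga <- generic_anthropometry()
  seg <- function(name, parent, coord, dir, jx, jy, comx, comy, mass, inertia) {
    data.frame(name = name, parent = parent, coord = coord, dir = dir,
               jx = jx, jy = jy, comx = comx, comy = comy, mass = mass,
               inertia = inertia, stringsAsFactors = FALSE)
  }
  segments <- rbind(
    seg("pelvis",     NA,           NA,            -1, 0,  0,     0,    0.05, 10.69, 0.107),
    seg("torso",      "pelvis",     "lumbar",      -1, 0,  0.10,  0,    0.25, 36.13, 1.340),
    seg("thigh_r",    "pelvis",     "hip_r",       +1, 0,  0,     0,   -0.18,  9.30, 0.141),
    seg("shank_r",    "thigh_r",    "knee_r",      -1, 0, -0.41,  0,   -0.18,  3.69, 0.056),
    seg("hindfoot_r", "shank_r",    "ankle_r",     +1, 0, -0.41,  0.02,-0.04,  0.90, 0.0023),
    seg("forefoot_r", "hindfoot_r", "mt_r",        +1, 0.10, -0.03, 0.04, -0.02, 0.35, 0.0006),
    seg("thigh_l",    "pelvis",     "hip_l",       +1, 0,  0,     0,   -0.18,  9.30, 0.141),
    seg("shank_l",    "thigh_l",    "knee_l",      -1, 0, -0.41,  0,   -0.18,  3.69, 0.056),
    seg("hindfoot_l", "shank_l",    "ankle_l",     +1, 0, -0.41,  0.02,-0.04,  0.90, 0.0023),
    seg("forefoot_l", "hindfoot_l", "mt_l",        +1, 0.10, -0.03, 0.04, -0.02, 0.35, 0.0006))

  mus <- function(name, side, f_max, l_opt, l_slack, v_max,
                  r_lumbar = 0, r_hip = 0, r_knee = 0, r_ankle = 0, r_mt = 0) {
    data.frame(name = name, side = side, f_max = f_max, l_opt = l_opt,
               l_slack = l_slack, penn_opt = 0, v_max = v_max,
               active_scale = 1, passive_shift = 0, rigid_tendon = TRUE,
               tendon_shape = 35,
               r_lumbar = r_lumbar, r_hip = r_hip, r_knee = r_knee,
               r_ankle = r_ankle, r_mt = r_mt, stringsAsFactors = FALSE)
  }
  leg <- function(side) rbind(
    mus("glut_max", side, 3000, 0.14, 0.125, 10, r_hip = -0.06),
    mus("iliopsoas", side, 2500, 0.10, 0.16, 10, r_hip = +0.05),
    mus("hamstrings", side, 3000, 0.10, 0.33, 10, r_hip = -0.06, r_knee = +0.03),
    mus("rectus_fem", side, 1500, 0.11, 0.32, 10, r_hip = +0.04, r_knee = -0.04),
    mus("vasti", side, 5000, 0.09, 0.22, 10, r_knee = -0.04),
    mus("gastroc", side, 3000, 0.06, 0.38, 10, r_knee = +0.02, r_ankle = -0.05),
    mus("soleus", side, 4000, 0.05, 0.25, 10, r_ankle = -0.05),
    # tibialis anterior lumped with the toe extensors: small midtarsal
    # dorsiflexion arm so the arch has antagonists in both directions
    mus("tib_ant", side, 1500, 0.07, 0.22, 10, r_ankle = +0.04,
        r_mt = +0.015),
    # intrinsic foot muscles are the main active arch stiffener (their
    # activation resists midtarsal dorsiflexion / arch drop)
    mus("foot_intrinsic", side, 2000, 0.05, 0.10, 10, r_mt = -0.03))
  muscles <- rbind(
    leg("r"), leg("l"),
    mus("back_ext", "c", 3000, 0.12, 0.10, 10, r_lumbar = -0.05),
    mus("abdominal", "c", 2000, 0.12, 0.12, 10, r_lumbar = +0.05))
  muscles$lref <- muscles$l_opt + muscles$l_slack

  sphere <- function(name, segment, x, y, r) {
    data.frame(name = name, segment = segment, x = x, y = y, radius = r,
               stringsAsFactors = FALSE)
  }
  contact <- rbind(
    sphere("heel_r", "hindfoot_r", -0.05, -0.04, 0.02),
    sphere("mid_r", "forefoot_r", 0.02, -0.01, 0.02),
    sphere("toe_r", "forefoot_r", 0.10, -0.01, 0.02),
    sphere("heel_l", "hindfoot_l", -0.05, -0.04, 0.02),
    sphere("mid_l", "forefoot_l", 0.02, -0.01, 0.02),
    sphere("toe_l", "forefoot_l", 0.10, -0.01, 0.02))

  pas <- function(coord, k1l, k2l, qlow, k1h, k2h, qhigh, damping) {
    data.frame(coord = coord, k1_low = k1l, k2_low = k2l, q_low = qlow,
               k1_high = k1h, k2_high = k2h, q_high = qhigh,
               damping = damping, stringsAsFactors = FALSE)
  }
  passive <- rbind(
    pas("lumbar", 10, 10, -0.25, 10, 10, 0.25, 1.0),
    pas("hip_r", 2, 5, -0.25, 2, 5, 2.0, 0.2),
    pas("hip_l", 2, 5, -0.25, 2, 5, 2.0, 0.2),
    pas("knee_r", 1, 10, 0.0, 2, 5, 2.2, 0.2),
    pas("knee_l", 1, 10, 0.0, 2, 5, 2.2, 0.2),
    pas("ankle_r", 1, 8, -0.6, 1, 8, 0.6, 0.2),
    pas("ankle_l", 1, 8, -0.6, 1, 8, 0.6, 0.2),
    pas("mt_r", 1, 10, -0.10, 2, 10, 0.15, 0.05),
    pas("mt_l", 1, 10, -0.10, 2, 10, 0.15, 0.05))

  structure(list(
    segments = segments, muscles = muscles, contact = contact,
    passive = passive,
    contact_params = list(stiffness = 1e5, dissipation = 2.0, friction = 0.8,
                          v_smooth = 0.05),
    height_m = ga$height_m, mass_kg = ga$mass_kg,
    gravity = 9.81
  ), class = "planar_model")
}

#' Validate a planar model
#' @param model a `planar_model`
#' @return the model, invisibly
#' @export
validate_model <- function(model) {
  if (!inherits(model, "planar_model")) stop_field("model", "not a planar_model")
  s <- model$segments
  if (!identical(s$name, SEGMENT_NAMES)) {
    stop_field("segments", "unexpected segment set or order")
  }
  if (any(s$mass <= 0) || any(s$inertia <= 0)) {
    stop_field("segments", "masses and inertias must be > 0")
  }
  m <- model$muscles
  if (any(m$f_max <= 0) || any(m$l_opt <= 0) || any(m$l_slack <= 0) ||
      any(m$v_max <= 0)) {
    stop_field("muscles", "f_max, l_opt, l_slack, v_max must be > 0")
  }
  if (any(m$active_scale < 0 | m$active_scale > 1)) {
    stop_field("active_scale", "sigma must lie in [0, 1]")
  }
  if (any(m$passive_shift < 0 | m$passive_shift > 0.6)) {
    stop_field("passive_shift", "shift must lie in [0, 0.6]")
  }
  if (any(m$penn_opt < 0 | m$penn_opt >= pi / 3)) {
    stop_field("penn_opt", "pennation must lie in [0, pi/3)")
  }
  if (any(model$contact$radius <= 0)) stop_field("contact", "radii must be > 0")
  arm_cols <- grep("^r_", names(m))
  if (any(rowSums(m[, arm_cols] != 0) < 1)) {
    stop_field("muscles", "every muscle must span at least one joint")
  }
  invisible(model)
}

#' Total model mass
#' @param model a `planar_model`
#' @return total mass in kg
#' @export
model_mass <- function(model) sum(model$segments$mass)

# Map a muscle row + side to its full 12-coordinate moment-arm vector.
muscle_arm_row <- function(mrow) {
  r <- numeric(length(COORD_NAMES))
  names(r) <- COORD_NAMES
  side <- mrow$side
  r["lumbar"] <- mrow$r_lumbar
  if (side %in% c("r", "l")) {
    r[paste0("hip_", side)] <- mrow$r_hip
    r[paste0("knee_", side)] <- mrow$r_knee
    r[paste0("ankle_", side)] <- mrow$r_ankle
    r[paste0("mt_", side)] <- mrow$r_mt
  }
  r
}

#' Pack a planar model into the flat numeric form used by the C++ core
#' @param model a validated `planar_model`
#' @return list of matrices/vectors consumed by the compiled routines
#' @keywords internal
pack_model <- function(model) {
  validate_model(model)
  s <- model$segments
  coord_idx <- function(nm) ifelse(is.na(nm), -1L, match(nm, COORD_NAMES) - 1L)
  seg <- cbind(
    parent = ifelse(is.na(s$parent), -1L, match(s$parent, s$name) - 1L),
    coord = coord_idx(s$coord), dir = s$dir, jx = s$jx, jy = s$jy,
    comx = s$comx, comy = s$comy, mass = s$mass, inertia = s$inertia)
  m <- model$muscles
  marm <- t(vapply(seq_len(nrow(m)), function(i) muscle_arm_row(m[i, ]),
                   numeric(length(COORD_NAMES))))
  ct <- model$contact
  contact <- cbind(body = match(ct$segment, s$name) - 1L,
                   cx = ct$x, cy = ct$y, radius = ct$radius)
  p <- model$passive
  passive <- cbind(coord = match(p$coord, COORD_NAMES) - 1L,
                   k1l = p$k1_low, k2l = p$k2_low, qlow = p$q_low,
                   k1h = p$k1_high, k2h = p$k2_high, qhigh = p$q_high,
                   damp = p$damping)
  list(nq = length(COORD_NAMES), seg = seg,
       fmax = m$f_max, lopt = m$l_opt, lslack = m$l_slack, vmax = m$v_max,
       sigma = m$active_scale, shift = m$passive_shift, lref = m$lref,
       marm = marm, contact = contact,
       contact_k = model$contact_params$stiffness,
       contact_damp = model$contact_params$dissipation,
       contact_mu = model$contact_params$friction,
       contact_vsmooth = model$contact_params$v_smooth,
       passive = passive, gravity = model$gravity)
}

#' Check left/right parameter symmetry of a model
#'
#' Mirrors every right-side muscle, segment and contact parameter onto its
#' left counterpart and reports whether all pairs agree.
#'
#' @param model a `planar_model`
#' @param tol numeric tolerance
#' @return TRUE/FALSE
#' @export
model_is_symmetric <- function(model, tol = 1e-12) {
  m <- model$muscles
  num <- vapply(m, is.numeric, logical(1))
  for (nm in LEG_MUSCLES) {
    r <- m[m$name == nm & m$side == "r", num]
    l <- m[m$name == nm & m$side == "l", num]
    if (max(abs(as.numeric(r) - as.numeric(l))) > tol) return(FALSE)
  }
  s <- model$segments
  pairs <- list(c("thigh_r", "thigh_l"), c("shank_r", "shank_l"),
                c("hindfoot_r", "hindfoot_l"), c("forefoot_r", "forefoot_l"))
  for (p in pairs) {
    a <- s[s$name == p[1], c("jx", "jy", "comx", "comy", "mass", "inertia")]
    b <- s[s$name == p[2], c("jx", "jy", "comx", "comy", "mass", "inertia")]
    if (max(abs(as.numeric(a) - as.numeric(b))) > tol) return(FALSE)
  }
  ct <- model$contact
  for (p in list(c("heel_r", "heel_l"), c("mid_r", "mid_l"),
                 c("toe_r", "toe_l"))) {
    a <- ct[ct$name == p[1], c("x", "y", "radius")]
    b <- ct[ct$name == p[2], c("x", "y", "radius")]
    if (max(abs(as.numeric(a) - as.numeric(b))) > tol) return(FALSE)
  }
  TRUE
}

#' Write a planar model to a YAML file
#' @param model a `planar_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model_yaml <- function(model, path) {
  obj <- list(
    type = "planar_model",
    height_m = model$height_m, mass_kg = model$mass_kg,
    gravity = model$gravity,
    contact_params = model$contact_params,
    segments = lapply(seq_len(nrow(model$segments)), function(i)
      as.list(model$segments[i, ])),
    muscles = lapply(seq_len(nrow(model$muscles)), function(i)
      as.list(model$muscles[i, ])),
    contact = lapply(seq_len(nrow(model$contact)), function(i)
      as.list(model$contact[i, ])),
    passive = lapply(seq_len(nrow(model$passive)), function(i)
      as.list(model$passive[i, ])))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a planar model from a YAML file written by [write_model_yaml()]
#' @param path input file path
#' @return a `planar_model`
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$type, "planar_model")) {
    stop_field("path", "not a planar_model file")
  }
  fix_na <- function(df) {
    df$parent[df$parent == "NA"] <- NA
    df
  }
  rowbind <- function(lst) do.call(rbind, lapply(lst, function(r) {
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  model <- structure(list(
    segments = rowbind(obj$segments),
    muscles = rowbind(obj$muscles),
    contact = rowbind(obj$contact),
    passive = rowbind(obj$passive),
    contact_params = obj$contact_params,
    height_m = obj$height_m, mass_kg = obj$mass_kg,
    gravity = obj$gravity), class = "planar_model")
  validate_model(model)
  model
}

#' Digest (hash) of a model's numeric content
#'
#' Stable content fingerprint used in run manifests; a short hex string
#' derived from the packed numeric representation.
#' @param model a `planar_model`
#' @return character scalar
#' @export
model_digest <- function(model) {
  pk <- pack_model(model)
  v <- unlist(lapply(pk, as.numeric), use.names = FALSE)
  bytes <- as.integer(serialize(round(v, 12), NULL, version = 2))
  # polynomial rolling hash in double arithmetic; no external digest needed
  h <- 0
  for (b in bytes[-(1:14)]) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.planar_model <- function(x, ...) {
  cat(sprintf("<planar_model> %.2f m, %.1f kg, %d segments, %d muscles\n",
              x$height_m, model_mass(x), nrow(x$segments), nrow(x$muscles)))
  imp <- x$muscles$active_scale < 1 | x$muscles$passive_shift > 0
  if (any(imp)) {
    cat("  impaired muscles:\n")
    print(x$muscles[imp, c("name", "side", "active_scale", "passive_shift")],
          row.names = FALSE)
  } else {
    cat("  no impairments (typically developing reference)\n")
  }
  invisible(x)
}
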