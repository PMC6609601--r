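#' Build the stylized 5-year-old head/neck voxel phantom
#'
#' Constructs a deterministic voxel phantom of the head and neck of a
#' 5-year-old (about 19 kg, 109 cm standing height), in the body frame used
#' throughout the package (origin at the whole-body centre, X left-right,
#' Y posterior-anterior, Z inferior-superior; the dental arch sits near
#' `(0, -3, 47)`). The anatomy is stylized — quadric shells and cylinders,
#' not CT-derived — but places every tallied tissue where the rotating
#' narrow beam of panoramic radiography meets it: cranial vault (calvarium)
#' around an ellipsoidal brain, a horseshoe mandible ("ramus" region) with
#' oral mucosa lining and a sublingual floor-of-mouth gland, parotid and
#' submandibular glands beside/below the mandible, cervical spine,
#' oesophagus segment, thyroid lobes, an extrathoracic-airway box
#' (nasal/pharyngeal lining), an outer skin shell, and neck muscle/lymph
#' soft tissue.
#'
#' Materials are air, soft tissue, bone and brain-equivalent tissue; organ
#' masses follow from voxel counts times nominal densities.
#'
#' @param voxel_cm Voxel edge length in cm (default 0.5). Values above 1 cm
#'   cannot resolve the thinnest organ (the sublingual gland) and are
#'   refused.
#' @return Object of class `ppd_phantom`: list with integer arrays
#'   `material` (0 air, 1 soft tissue, 2 bone, 3 brain) and `organ`
#'   (0 = unlabelled) as vectors in x-fastest order, `dims`, `origin`
#'   (corner, cm), `voxel_cm`, `organs` (label names), `organ_mass_g`.
#' @export
build_pediatric_phantom <- function(voxel_cm = 0.5) {
  if (voxel_cm <= 0) stop("voxel_cm must be positive")
  if (voxel_cm > 1)
    stop("voxel_cm too coarse to resolve the sublingual gland (max 1 cm)")
  origin <- c(-10, -12, 36)
  upper <- c(10, 10, 56)
  dims <- as.integer(round((upper - origin) / voxel_cm))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- origin[1] + (seq_len(nx) - 0.5) * voxel_cm
  cy <- origin[2] + (seq_len(ny) - 0.5) * voxel_cm
  cz <- origin[3] + (seq_len(nz) - 0.5) * voxel_cm
  x <- rep(cx, times = ny * nz)
  y <- rep(rep(cy, each = nx), times = nz)
  z <- rep(cz, each = nx * ny)

  ell <- function(cxo, cyo, czo, ax, ay, az)
    ((x - cxo) / ax)^2 + ((y - cyo) / ay)^2 + ((z - czo) / az)^2 <= 1

  head <- ell(0, -2, 47.5, 6.5, 8, 8)
  neck <- (x^2 + (y + 2)^2 <= 4.5^2) & z <= 41.5
  body <- head | neck

  material <- integer(length(x))       # 0 = air
  organ <- integer(length(x))
  material[body] <- 1L                 # soft tissue

  organs <- c("brain", "calvarium", "ramus", "cervical_spine", "thyroid",
              "oesophagus", "parotid", "submandibular", "sublingual",
              "oral_mucosa", "extrathoracic_airway", "skin", "muscle_lymph")
  oid <- function(name) match(name, organs)
  assign_organ <- function(sel, name, mat = NULL) {
    sel <- sel & body & organ == 0L
    organ[sel] <<- oid(name)
    if (!is.null(mat)) material[sel] <<- mat
  }

  # brain + cranial vault, clamped above the dental-arch plane so the
  # small head leaves room for the oral region below the cranial base
  brain <- ell(0, -2, 50, 5.4, 6.4, 6.0) & z >= 47.6
  assign_organ(brain, "brain", 3L)
  vault <- ell(0, -2, 50, 6.0, 7.0, 6.6) & !brain & z >= 47.6
  assign_organ(vault, "calvarium", 2L)

  # dental arch: horseshoe mandible with mucosal lining and tongue space
  r_arch <- sqrt(x^2 + (y + 3)^2)
  front <- (y + 3) >= -0.35 * pmax(r_arch, 1e-9)
  assign_organ(r_arch >= 3.4 & r_arch <= 4.4 & front &
                 z >= 44.5 & z <= 47, "ramus", 2L)
  assign_organ(r_arch >= 2.5 & r_arch < 3.4 & front &
                 z >= 45 & z <= 47.5, "oral_mucosa")
  assign_organ(r_arch < 2.5 & z >= 45 & z <= 46 & (y + 3) >= -1, "sublingual")

  # glands
  assign_organ(ell(5.0, -5, 46, 0.9, 1.3, 1.6) |
                 ell(-5.0, -5, 46, 0.9, 1.3, 1.6), "parotid")
  assign_organ(ell(3.2, -2.5, 43.8, 0.9, 0.9, 0.8) |
                 ell(-3.2, -2.5, 43.8, 0.9, 0.9, 0.8), "submandibular")

  # neck organs
  assign_organ(x^2 + (y + 5.5)^2 <= 1.1^2 & z <= 44.5, "cervical_spine", 2L)
  assign_organ(x^2 + (y + 3.8)^2 <= 0.8^2 & z <= 41, "oesophagus")
  assign_organ(ell(1.3, 0.8, 38.8, 0.8, 0.6, 1.1) |
                 ell(-1.3, 0.8, 38.8, 0.8, 0.6, 1.1), "thyroid")

  # extrathoracic airway lining (nasal cavity / nasopharynx block)
  assign_organ(abs(x) <= 1.4 & y >= 1.2 & y <= 4.8 &
                 z >= 46 & z <= 50, "extrathoracic_airway")

  # skin: fixed 0.4 cm geometric shell just inside the body surface, so
  # its mass is independent of the voxel resolution
  shell <- 0.4
  head_in <- ell(0, -2, 47.5, 6.5 - shell, 8 - shell, 8 - shell)
  neck_in <- (x^2 + (y + 2)^2 <= (4.5 - shell)^2) & z <= 41.5
  surface <- body & !(head_in | neck_in) & z > 37  # skip the cut base plane
  assign_organ(surface, "skin")

  # remaining neck soft tissue stands in for muscle / lymph-node regions
  assign_organ(material == 1L & z <= 42.5, "muscle_lymph")

  dens <- c(0, ppd_densities[["soft_tissue"]], ppd_densities[["bone"]],
            ppd_densities[["brain"]])
  vol <- voxel_cm^3
  mass <- vapply(seq_along(organs), function(i)
    sum(dens[material[organ == i] + 1L]) * vol, numeric(1))
  names(mass) <- organs
  if (any(mass <= 0))
    stop("phantom construction failed: zero-mass organ(s): ",
         paste(organs[mass <= 0], collapse = ", "))

  structure(list(material = material, organ = organ, dims = dims,
                 origin = origin, voxel_cm = voxel_cm, organs = organs,
                 organ_mass_g = mass),
            class = "ppd_phantom")
}

#' @export
print.ppd_phantom <- function(x, ...) {
  cat(sprintf("Stylized 5-year-old head/neck phantom: %d x %d x %d voxels @ %g cm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_cm))
  cat("Organ masses (g):\n")
  print(round(x$organ_mass_g, 1))
  invisible(x)
}

# voxel index (1-based) of a point, NA if outside
phantom_voxel <- function(phantom, p) {
  ijk <- floor((p - phantom$origin) / phantom$voxel_cm) + 1
  if (any(ijk < 1) || any(ijk > phantom$dims)) return(NA_integer_)
  as.integer(ijk[1] + phantom$dims[1] * (ijk[2] - 1) +
               phantom$dims[1] * phantom$dims[2] * (ijk[3] - 1))
}
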