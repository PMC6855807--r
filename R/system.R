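# Coarse-grained system construction: rigid bodies from C-alpha coordinates,
# flexible residue strings initialised on an interpolated path.

#' Build a coarse-grained system model from a topology
#'
#' The topology declares components, rigid-body blocks and flexible ranges.
#' Rigid-body beads are placed on the C-alpha positions read from the named
#' PDB file/chain; flexible beads get one independently movable bead per
#' residue, initialised by linear interpolation between their anchoring rigid
#' beads with Gaussian jitter (sigma 1 Angstrom, drawn from the current RNG
#' stream), or on a 3.8 Angstrom random walk when unanchored.
#'
#' A topology is an R list (or the path of a YAML file) with entries:
#' \describe{
#'   \item{components}{list of \code{list(name=)} entries.}
#'   \item{rigid_bodies}{list of \code{list(name=, members=)}; each member is
#'     \code{list(component=, start=, end=, pdb=, chain=)}. A body with
#'     several members (possibly from different components or PDB files)
#'     forms one rigid unit, which is how a fused catalytic core
#'     (e.g. residues 133-368 as one block) or a helix grouped rigidly with
#'     its bound ubiquitin is declared; the split alternative simply lists
#'     two bodies and a two-residue flexible range between them.}
#'   \item{flexible}{list of \code{list(component=, start=, end=)} ranges.}
#' }
#' Residue ranges are 1-based and inclusive. Every declared residue is housed
#' in exactly one rigid body or flexible segment; overlaps are an error.
#'
#' @param topology list as above, or path to a YAML file.
#' @param pdbDir directory against which relative PDB paths are resolved.
#' @param beadRadius bead radius in Angstrom (scalar, default 3.0).
#' @return a [SystemModel-class]
#' @export
buildSystem <- function(topology, pdbDir = ".", beadRadius = 3.0) {
  if (is.character(topology) && length(topology) == 1)
    topology <- yaml::read_yaml(topology)
  bodies <- topology$rigid_bodies
  flex <- topology$flexible
  if (is.null(bodies)) bodies <- list()
  if (is.null(flex)) flex <- list()

  comp <- character(); res <- integer(); bodyId <- integer()
  coords <- matrix(numeric(0), 0, 3)
  bodyList <- list(); segList <- list()
  pdbCache <- new.env(parent = emptyenv())

  for (bi in seq_along(bodies)) {
    b <- bodies[[bi]]
    bname <- if (is.null(b$name)) paste0("body", bi) else b$name
    idx0 <- length(comp)
    for (m in b$members) {
      rng <- seq.int(m$start, m$end)
      xyz <- .caCoords(m, pdbDir, pdbCache)
      comp <- c(comp, rep(m$component, length(rng)))
      res <- c(res, as.integer(rng))
      coords <- rbind(coords, xyz)
    }
    beads <- seq.int(idx0 + 1L, length(comp))
    bodyId <- c(bodyId, rep(bi, length(beads)))
    bodyList[[bi]] <- list(name = bname, beads = beads,
                           rotation = diag(3), translation = c(0, 0, 0))
  }
  for (si in seq_along(flex)) {
    s <- flex[[si]]
    rng <- seq.int(s$start, s$end)
    idx0 <- length(comp)
    comp <- c(comp, rep(s$component, length(rng)))
    res <- c(res, as.integer(rng))
    coords <- rbind(coords, matrix(NA_real_, length(rng), 3))
    bodyId <- c(bodyId, rep(0L, length(rng)))
    segList[[si]] <- list(name = sprintf("%s_%d_%d", s$component, s$start, s$end),
                          beads = seq.int(idx0 + 1L, length(comp)))
  }

  dup <- duplicated(paste0(comp, ":", res))
  if (any(dup))
    stop("overlapping residue ranges in topology: ",
         paste(unique(paste0(comp[dup], ":", res[dup])), collapse = ", "))

  model <- new("SystemModel", coords = coords,
               radii = rep(beadRadius, length(comp)),
               component = comp, residue = as.integer(res),
               bodyId = as.integer(bodyId),
               bodies = bodyList, segments = segList)
  initializeFlexible(model)
}

# C-alpha coordinates for one rigid-body member, via bio3d
.caCoords <- function(m, pdbDir, cache) {
  path <- m$pdb
  if (!file.exists(path)) path <- file.path(pdbDir, m$pdb)
  if (!file.exists(path)) stop("PDB file not found: ", m$pdb)
  key <- normalizePath(path)
  pdb <- if (!is.null(cache[[key]])) cache[[key]] else {
    p <- bio3d::read.pdb(path, verbose = FALSE)
    cache[[key]] <- p
    p
  }
  chain <- if (is.null(m$chain)) pdb$atom$chain[1] else m$chain
  rng <- seq.int(m$start, m$end)
  sel <- pdb$atom$elety == "CA" & pdb$atom$chain == chain &
    pdb$atom$resno %in% rng
  at <- pdb$atom[sel, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  missing <- setdiff(rng, at$resno)
  if (length(missing))
    stop("missing C-alpha for rigid residue(s) ", m$component, ":",
         paste(missing, collapse = ","), " in ", basename(path),
         " chain ", chain)
  at <- at[match(rng, at$resno), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Initialise flexible-segment beads
#'
#' Places each flexible bead by linear interpolation between the nearest
#' housed residues flanking its segment in sequence (its anchors), plus
#' isotropic Gaussian jitter (sigma 1 Angstrom). Segments with a single
#' anchor extend from it as a 3.8 Angstrom random walk; fully unanchored
#' segments random-walk from the origin. Consumes the current RNG stream.
#'
#' @param model a [SystemModel-class] (flexible beads may hold NA coordinates)
#' @param jitterSd Gaussian jitter, Angstrom
#' @return the model with all flexible beads placed
#' @export
initializeFlexible <- function(model, jitterSd = 1.0) {
  stopifnot(is(model, "SystemModel"))
  coords <- model@coords
  key <- paste0(model@component, ":", model@residue)
  for (s in model@segments) {
    beads <- s$beads
    compS <- model@component[beads[1]]
    resRange <- model@residue[beads]
    pre <- match(paste0(compS, ":", min(resRange) - 1L), key)
    post <- match(paste0(compS, ":", max(resRange) + 1L), key)
    nb <- length(beads)
    if (!is.na(pre) && !is.na(post)) {
      a <- coords[pre, ]; b <- coords[post, ]
      frac <- seq_len(nb) / (nb + 1)
      base <- outer(frac, b - a) + matrix(a, nb, 3, byrow = TRUE)
      coords[beads, ] <- base + matrix(stats::rnorm(3 * nb, 0, jitterSd), nb, 3)
    } else {
      anchor <- if (!is.na(pre)) coords[pre, ]
        else if (!is.na(post)) coords[post, ] else c(0, 0, 0)
      walkFrom <- anchor
      ord <- if (is.na(pre) && !is.na(post)) rev(seq_len(nb)) else seq_len(nb)
      for (i in ord) {
        step <- stats::rnorm(3)
        walkFrom <- walkFrom + 3.8 * step / sqrt(sum(step^2))
        coords[beads[i], ] <- walkFrom
      }
    }
  }
  model@coords <- coords
  validObject(model)
  model
}

#' Apply a rigid transform to one rigid body
#'
#' Transforms every bead x of the named body to \code{R x + t} (rotation
#' about the origin, then translation) and composes the body pose
#' accordingly. All other beads are untouched; the body's internal geometry
#' is preserved exactly.
#'
#' @param model a [SystemModel-class]
#' @param body rigid-body name
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1, checked
#'   to 1e-9)
#' @param translation length-3 numeric, Angstrom
#' @return the transformed [SystemModel-class]
#' @export
applyTransform <- function(model, body, rotation, translation = c(0, 0, 0)) {
  stopifnot(is(model, "SystemModel"))
  i <- match(body, bodyNames(model))
  if (is.na(i)) stop("unknown rigid body: ", body)
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with det +1 (tolerance 1e-9)")
  b <- model@bodies[[i]]
  model@coords[b$beads, ] <- t(rotation %*% t(model@coords[b$beads, , drop = FALSE])) +
    matrix(translation, length(b$beads), 3, byrow = TRUE)
  model@bodies[[i]]$rotation <- rotation %*% b$rotation
  model@bodies[[i]]$translation <- as.numeric(rotation %*% b$translation) + translation
  model
}

#' C-alpha (bead) distance between two residues
#'
#' @param model a [SystemModel-class]
#' @param a,b residue references: \code{c(component, residue)} or a
#'   \code{"component:residue"} string
#' @return Euclidean distance in Angstrom
#' @export
caDistance <- function(model, a, b) {
  ia <- .resolveResidue(model, a)
  ib <- .resolveResidue(model, b)
  sqrt(sum((model@coords[ia, ] - model@coords[ib, ])^2))
}

.resolveResidue <- function(model, ref) {
  if (length(ref) == 1 && grepl(":", ref)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    ref <- c(parts[1], parts[2])
  }
  beadIndex(model, ref[1], as.integer(ref[2]))
}

#' Uniformly random rotation matrix
#'
#' Random rotation via a quaternion with i.i.d. normal components
#' (Haar-uniform over SO(3)); with \code{maxAngle} given, instead a rotation
#' about a uniformly random axis by an angle uniform on \code{[0, maxAngle]}.
#'
#' @param maxAngle optional maximum rotation angle, radians
#' @return 3x3 rotation matrix
#' @export
randomRotation <- function(maxAngle = NULL) {
  if (is.null(maxAngle)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    return(.quatToMatrix(q))
  }
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rotationAboutAxis(ax, stats::runif(1, 0, maxAngle))
}

.quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotation about an axis (Rodrigues formula)
#'
#' @param axis length-3 vector (normalised internally)
#' @param angle radians
#' @return 3x3 rotation matrix
#' @export
rotationAboutAxis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# ---- bead-model PDB input/output ----

#' Write a bead model (or several) as a PDB file
#'
#' One CA atom record per bead; multiple configurations are written as
#' MODEL/ENDMDL blocks. Components are mapped to chain identifiers in order
#' of appearance. Coordinates are written at the PDB precision (1e-3
#' Angstrom).
#'
#' @param model a [SystemModel-class] providing the bead bookkeeping
#' @param file output path
#' @param coords optional: a 3-column matrix, a list of such matrices, or an
#'   (n x 3 x m) array of configurations; defaults to the model's coordinates
#' @param bFactor optional numeric vector (one value per bead) written to the
#'   B-factor field; \code{NA} entries get occupancy 0 and B-factor 0,
#'   marking beads without an annotation
#' @return \code{file}, invisibly
#' @export
writeModelPDB <- function(model, file, coords = NULL, bFactor = NULL) {
  stopifnot(is(model, "SystemModel"))
  if (is.null(coords)) coords <- model@coords
  if (is.matrix(coords)) coords <- list(coords)
  if (is.array(coords) && length(dim(coords)) == 3)
    coords <- lapply(seq_len(dim(coords)[3]), function(i) coords[, , i])
  n <- nBeads(model)
  chains <- LETTERS[match(model@component, unique(model@component))]
  occ <- rep(1, n); bf <- rep(0, n)
  if (!is.null(bFactor)) {
    occ <- ifelse(is.na(bFactor), 0, 1)
    bf <- ifelse(is.na(bFactor), 0, bFactor)
  }
  con <- file(file, "w")
  on.exit(close(con))
  multi <- length(coords) > 1
  for (mi in seq_along(coords)) {
    xyz <- coords[[mi]]
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), chains, model@residue, xyz[, 1], xyz[, 2], xyz[, 3], occ, bf)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Write rigid-body poses as JSON
#'
#' Serialises each body's cumulative pose (rotation matrix and translation
#' relative to the build coordinates) for provenance alongside a PDB.
#'
#' @param model a [SystemModel-class]
#' @param file output JSON path
#' @return \code{file}, invisibly
#' @export
writePoses <- function(model, file) {
  stopifnot(is(model, "SystemModel"))
  poses <- lapply(model@bodies, function(b)
    list(name = b$name, rotation = b$rotation,
         translation = b$translation, n_beads = length(b$beads)))
  jsonlite::write_json(poses, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' Read bead-model coordinates written by [writeModelPDB()]
#'
#' @param file PDB path
#' @return an (n beads x 3 x n models) array
#' @export
readModelCoords <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  m <- nrow(xyz); n <- ncol(xyz) / 3
  arr <- array(NA_real_, c(n, 3, m))
  for (i in seq_len(m))
    arr[, , i] <- matrix(xyz[i, ], n, 3, byrow = TRUE)
  arr
}
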