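#' @useDynLib adcomplement, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot setNames
NULL

# Default per-bead parameters applied when no sidecar value is available.
.default_bead <- list(charge = 0, vdw_radius = 1.7, lj_epsilon = 0.1, lj_rmin = 3.4)

#' Construct a molecular model
#'
#' A `MolecularModel` is the universal structure container of the package: a
#' flat atom table (one pseudo-atom per coarse-grained residue bead) plus
#' per-chain role and domain annotations. Chain roles name what the chain is
#' in the biology (`hexon`, `penton_base`, `fiber`, `igm_fc`, `igm_fab`,
#' `c1q`, `c1r`, `c1s`, `c4b_alpha`, `c4b_beta`, `c3b_alpha`, `c3b_beta`,
#' `fx_gla`, `fx_protease`); domain annotations are named residue ranges
#' (e.g. the penton-base `rgd_loop`, residues 297-376).
#'
#' @param name model name.
#' @param atoms data frame with columns `serial`, `name`, `element`, `x`,
#'   `y`, `z`, `vdw_radius`, `charge`, `lj_epsilon`, `lj_rmin`,
#'   `residue_index`, `chain_id`. Missing parameter columns are filled with
#'   defaults (charge 0, radius 1.7 A, epsilon 0.1 kcal/mol, Rmin 3.4 A).
#' @param chains named list `chain_id -> list(role =, domains = list(name =
#'   c(start, end)))`.
#' @param metadata free-form list (provenance, calibration constants, frames).
#' @return object of class `MolecularModel`.
#' @export
molecular_model <- function(name, atoms = NULL, chains = list(), metadata = list()) {
  if (is.null(atoms)) {
    atoms <- data.frame(
      serial = integer(), name = character(), element = character(),
      x = numeric(), y = numeric(), z = numeric(),
      vdw_radius = numeric(), charge = numeric(),
      lj_epsilon = numeric(), lj_rmin = numeric(),
      residue_index = integer(), chain_id = character(),
      stringsAsFactors = FALSE
    )
  }
  for (col in c("vdw_radius", "charge", "lj_epsilon", "lj_rmin")) {
    if (is.null(atoms[[col]])) {
      atoms[[col]] <- rep(.default_bead[[sub("vdw_radius", "vdw_radius", col)]], nrow(atoms))
    }
  }
  if (is.null(atoms$name)) atoms$name <- rep("CA", nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- rep("C", nrow(atoms))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  m <- structure(
    list(name = name, atoms = atoms, chains = chains, metadata = metadata),
    class = "MolecularModel"
  )
  validate_model(m)
  m
}

#' Validate a molecular model
#'
#' Checks the container invariants: unique serials, finite coordinates,
#' positive radii, strictly increasing residue indices within each chain, and
#' domain annotations lying inside their chain's residue span.
#'
#' @param m a `MolecularModel`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_model <- function(m) {
  a <- m$atoms
  if (nrow(a) > 0) {
    if (anyDuplicated(a$serial)) stop("atom serials not unique in model '", m$name, "'")
    if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates in model '", m$name, "'")
    if (any(a$vdw_radius <= 0)) stop("vdw_radius must be > 0")
    if (any(a$lj_rmin <= 0)) stop("lj_rmin must be > 0")
    if (any(a$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  }
  if (anyDuplicated(names(m$chains))) stop("chain ids not unique in model '", m$name, "'")
  if (nrow(a) > 0) {
    for (cid in unique(a$chain_id)) {
      res <- a$residue_index[a$chain_id == cid]
      if (length(res) > 1 && any(diff(unique_preserve(res)) <= 0)) {
        stop("residue indices not strictly increasing in chain ", cid)
      }
    }
  }
  for (cid in names(m$chains)) {
    idx <- which(a$chain_id == cid)
    res <- a$residue_index[idx]
    dom <- m$chains[[cid]]$domains
    if (length(idx) > 0 && length(dom) > 0) {
      span <- range(res)
      for (dn in names(dom)) {
        d <- dom[[dn]]
        if (d[1] < span[1] || d[2] > span[2]) {
          stop("domain '", dn, "' range [", d[1], ",", d[2],
               "] outside residue span of chain ", cid)
        }
      }
    }
  }
  invisible(m)
}

# residue order as encountered (beads appear once per residue)
unique_preserve <- function(x) x[!duplicated(x)]

#' @export
print.MolecularModel <- function(x, ...) {
  cat("MolecularModel '", x$name, "': ", nrow(x$atoms), " atoms, ",
      length(x$chains), " chains\n", sep = "")
  invisible(x)
}

#' Number of atoms in a model
#' @param m a `MolecularModel`.
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Coordinate matrix of a model
#' @param m a `MolecularModel`.
#' @param idx optional row indices.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(m, idx = NULL) {
  a <- m$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Replace coordinates of a model
#' @param m a `MolecularModel`.
#' @param xyz n x 3 matrix matching the atom count.
#' @return updated model.
#' @export
set_coords <- function(m, xyz) {
  stopifnot(nrow(xyz) == nrow(m$atoms))
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

#' Centroid of a model (or of selected atoms)
#' @param m a `MolecularModel`.
#' @param idx optional atom row indices.
#' @return length-3 numeric vector.
#' @export
model_centroid <- function(m, idx = NULL) colMeans(coords(m, idx))

#' Select atom rows by chain, residue range, role or domain annotation
#'
#' @param m a `MolecularModel`.
#' @param chain optional chain id(s).
#' @param role optional chain role(s).
#' @param residues optional residue index vector or `c(start, end)` range
#'   applied with `range = TRUE`.
#' @param domain optional domain annotation name; selects the annotated
#'   residue range within the matching chains.
#' @param range interpret `residues` as an inclusive range.
#' @return integer vector of atom row indices.
#' @export
select_atoms <- function(m, chain = NULL, role = NULL, residues = NULL,
                         domain = NULL, range = FALSE) {
  a <- m$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) {
    ids <- names(m$chains)[vapply(m$chains, function(ch) ch$role %in% role, logical(1))]
    keep <- keep & a$chain_id %in% ids
  }
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(domain)) {
    dkeep <- rep(FALSE, nrow(a))
    for (cid in names(m$chains)) {
      dom <- m$chains[[cid]]$domains[[domain]]
      if (!is.null(dom)) {
        dkeep <- dkeep | (a$chain_id == cid &
                          a$residue_index >= dom[1] & a$residue_index <= dom[2])
      }
    }
    keep <- keep & dkeep
  }
  if (!is.null(residues)) {
    if (range) {
      keep <- keep & a$residue_index >= residues[1] & a$residue_index <= residues[2]
    } else {
      keep <- keep & a$residue_index %in% residues
    }
  }
  which(keep)
}

#' Extract a sub-model by atom indices
#' @param m a `MolecularModel`.
#' @param idx atom row indices to keep.
#' @param name optional new name.
#' @return `MolecularModel` with only the selected atoms and their chains.
#' @export
model_subset <- function(m, idx, name = m$name) {
  a <- m$atoms[idx, , drop = FALSE]
  rownames(a) <- NULL
  keep_chains <- m$chains[intersect(names(m$chains), unique(a$chain_id))]
  # drop domain annotations that no longer fit the retained span
  for (cid in names(keep_chains)) {
    res <- a$residue_index[a$chain_id == cid]
    span <- range(res)
    dom <- keep_chains[[cid]]$domains
    dom <- dom[vapply(dom, function(d) d[1] >= span[1] && d[2] <= span[2], logical(1))]
    keep_chains[[cid]]$domains <- dom
  }
  molecular_model(name, a, keep_chains, m$metadata)
}

#' Merge several models into one
#'
#' Chain ids are prefixed with each model's name when `prefix = TRUE` so that
#' merged assemblies keep unique chain ids; serials are renumbered.
#'
#' @param models list of `MolecularModel`s.
#' @param name name for the merged model.
#' @param prefix prefix chain ids with model names.
#' @return merged `MolecularModel`.
#' @export
merge_models <- function(models, name = "assembly", prefix = TRUE) {
  models <- models[vapply(models, Negate(is.null), logical(1))]
  atoms <- list(); chains <- list()
  for (m in models) {
    a <- m$atoms
    ch <- m$chains
    if (prefix) {
      map <- setNames(paste0(m$name, ".", names(ch)), names(ch))
      a$chain_id <- unname(map[a$chain_id])
      names(ch) <- unname(map)
    }
    atoms[[length(atoms) + 1]] <- a
    chains <- c(chains, ch)
  }
  a <- do.call(rbind, atoms)
  if (is.null(a)) return(molecular_model(name))
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  molecular_model(name, a, chains)
}
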