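# PDB ATOM-record I/O (wwPDB v3.3 fixed columns) plus a JSON sidecar carrying
# chain roles, domain ranges and bead parameters. Bead parameters are keyed by
# bead type (the atom-name field), so charged marker beads use distinct names
# (e.g. "NEG", "POS") while plain backbone beads are "CA". Chain ids longer
# than one character are stored in the segment-id columns (73-76); ids longer
# than four characters get compact segids with the mapping recorded in the
# sidecar, so arbitrary assembly chain ids round-trip exactly.

# ---- hybrid-36 serials -------------------------------------------------------
# Width-5 serial field: 1..99999 decimal, then upper-case base36 from A0000,
# then lower-case. Assembled facets exceed 99999 beads at fine spacing.

.h36_chars_u <- c(as.character(0:9), LETTERS)
.h36_chars_l <- c(as.character(0:9), letters)

.h36_to_string <- function(v, width, upper) {
  chars <- if (upper) .h36_chars_u else .h36_chars_l
  out <- character(width)
  for (k in width:1) {
    out[k] <- chars[(v %% 36) + 1]
    v <- v %/% 36
  }
  paste(out, collapse = "")
}

hy36_encode <- function(x, width = 5) {
  base <- 36^(width - 1)
  block <- 26 * base
  vapply(x, function(v) {
    if (v < 10^width) {
      formatC(v, width = width, format = "d")
    } else if (v < 10^width + block) {
      .h36_to_string(v - 10^width + 10 * base, width, upper = TRUE)
    } else {
      .h36_to_string(v - 10^width - block + 10 * base, width, upper = FALSE)
    }
  }, character(1))
}

hy36_decode <- function(s) {
  vapply(s, function(str) {
    str <- trimws(str)
    if (grepl("^-?[0-9]+$", str)) return(as.numeric(str))
    width <- nchar(str)
    base <- 36^(width - 1)
    block <- 26 * base
    upper <- substr(str, 1, 1) %in% LETTERS
    chars <- if (upper) .h36_chars_u else .h36_chars_l
    digits <- match(strsplit(str, "")[[1]], chars) - 1
    if (anyNA(digits)) stop("invalid hybrid-36 serial '", str, "'")
    v <- sum(digits * 36^((width - 1):0))
    if (upper) v - 10 * base + 10^width
    else v - 10 * base + 10^width + block
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- write -------------------------------------------------------------------

sidecar_path <- function(path) {
  if (grepl("\\.pdb$", path)) sub("\\.pdb$", ".json", path) else paste0(path, ".json")
}

#' Write a model as PDB ATOM records plus JSON sidecar
#'
#' Emits standard fixed-column ATOM records (3-decimal coordinates, B-factor
#' 0.00) with hybrid-36 widening of serial numbers past 99,999 atoms, and a
#' JSON sidecar alongside (`.json` next to the `.pdb`) carrying chain roles,
#' domain annotations, bead parameters by bead type, and model metadata.
#'
#' @param model a `MolecularModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))

  cids <- if (length(model$chains)) names(model$chains) else unique(a$chain_id)
  long <- any(nchar(cids) > 4)
  segid_map <- if (long) {
    setNames(sprintf("S%03d", seq_along(cids)), cids)
  } else {
    setNames(cids, cids)
  }

  if (nrow(a) > 0) {
    serial <- hy36_encode(seq_len(nrow(a)))
    segid <- unname(segid_map[a$chain_id])
    chain1 <- substr(segid, 1, 1)
    lines <- sprintf(
      "ATOM  %5s %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
      serial, substr(a$name, 1, 4), "GLY", chain1, a$residue_index,
      a$x, a$y, a$z, 1.0, 0.0, segid, substr(a$element, 1, 2)
    )
    writeLines(lines, con)
  }
  writeLines("END", con)

  chains <- lapply(cids, function(cid) {
    ch <- model$chains[[cid]]
    list(role = if (is.null(ch$role)) "unknown" else ch$role,
         domains = if (is.null(ch$domains)) structure(list(), names = character())
                   else ch$domains,
         segid = unname(segid_map[[cid]]))
  })
  names(chains) <- cids

  beads <- list()
  if (nrow(a) > 0) {
    for (tp in unique(a$name)) {
      row <- a[match(tp, a$name), ]
      beads[[tp]] <- list(charge = row$charge, vdw_radius = row$vdw_radius,
                          lj_epsilon = row$lj_epsilon, lj_rmin = row$lj_rmin)
    }
  }
  side <- list(name = model$name, chains = chains, beads = beads,
               metadata = model$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- read --------------------------------------------------------------------

#' Read a PDB file (with optional JSON sidecar) into a model
#'
#' Parses ATOM/HETATM records; chain identity is taken from the segment-id
#' columns when present, else the chain-id column. Atoms lacking sidecar bead
#' parameters get the defaults (charge 0, radius 1.7 A, epsilon 0.1, Rmin
#' 3.4). Serial numbers (hybrid-36 if widened) are re-numbered sequentially.
#'
#' @param path PDB file path.
#' @param sidecar optional sidecar path; defaults to the `.json` next to
#'   `path` when that file exists.
#' @return a `MolecularModel`.
#' @export
read_structure <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sidecar) && file.exists(sidecar_path(path))) {
    sidecar <- sidecar_path(path)
  }
  side <- if (!is.null(sidecar)) jsonlite::read_json(sidecar) else NULL

  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  nm <- el <- cid <- character(length(sel))
  xs <- ys <- zs <- numeric(length(sel))
  ri <- integer(length(sel))
  for (k in seq_along(sel)) {
    ln <- lines[sel[k]]
    lineno <- sel[k]
    if (nchar(ln) < 54) {
      stop("malformed ATOM record at line ", lineno, ": too short")
    }
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    r <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(c(x, y, z))) {
      stop("malformed ATOM record at line ", lineno, ": bad coordinates")
    }
    if (is.na(r)) stop("malformed ATOM record at line ", lineno, ": bad residue index")
    nm[k] <- trimws(substr(ln, 13, 16))
    el[k] <- trimws(substr(ln, 77, 78))
    seg <- trimws(substr(ln, 73, 76))
    cid[k] <- if (nzchar(seg)) seg else trimws(substr(ln, 22, 22))
    xs[k] <- x; ys[k] <- y; zs[k] <- z; ri[k] <- r
  }

  chains <- list()
  if (!is.null(side$chains)) {
    segmap <- vapply(side$chains, function(ch) {
      if (is.null(ch$segid)) NA_character_ else ch$segid
    }, character(1))
    # restore full chain ids from segids
    if (!anyNA(segmap)) {
      lookup <- setNames(names(side$chains), unname(segmap))
      hit <- cid %in% names(lookup)
      cid[hit] <- unname(lookup[cid[hit]])
    }
    present <- unique(cid)
    for (full in names(side$chains)) {
      if (!(full %in% present)) {
        stop("sidecar chain '", full, "' not present in ", path)
      }
      ch <- side$chains[[full]]
      chains[[full]] <- list(
        role = ch$role,
        domains = lapply(ch$domains, function(d) as.numeric(unlist(d)))
      )
    }
  } else {
    for (u in unique(cid)) chains[[u]] <- list(role = "unknown", domains = list())
  }

  bead <- function(tp, field) {
    b <- side$beads[[tp]]
    if (is.null(b) || is.null(b[[field]])) .default_bead[[field]] else b[[field]]
  }
  atoms <- data.frame(
    serial = seq_along(sel), name = nm, element = ifelse(nzchar(el), el, "C"),
    x = xs, y = ys, z = zs,
    vdw_radius = vapply(nm, bead, numeric(1), field = "vdw_radius"),
    charge = vapply(nm, bead, numeric(1), field = "charge"),
    lj_epsilon = vapply(nm, bead, numeric(1), field = "lj_epsilon"),
    lj_rmin = vapply(nm, bead, numeric(1), field = "lj_rmin"),
    residue_index = ri, chain_id = cid, stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  meta <- if (!is.null(side$metadata)) side$metadata else list()
  name <- if (!is.null(side$name)) side$name else
    sub("\\.pdb$", "", basename(path))
  molecular_model(name, atoms, chains, meta)
}
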