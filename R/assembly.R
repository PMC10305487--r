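# Facet assembly: 18 hexon-trimer slots on a triangular close-packed lattice
# (12 canonical facet slots labelled by asymmetric-unit position 1-4 under
# the facet three-fold, plus 6 edge-extension slots completing the
# triangular array), penton pentamers at the three vertices, helically built
# fibers along the outward normal. Facet plane z = 0, outward normal +z,
# centroid at the origin.

#' Fiber build parameters
#'
#' @param rise shaft rise per repeat, Angstrom.
#' @param twist shaft twist per repeat, degrees.
#' @param n_total_repeats total shaft repeats in the built fiber.
#' @return object of class `FiberBuildParams`.
#' @export
fiber_build_params <- function(rise = 13, twist = 51.4, n_total_repeats = 21) {
  stopifnot(rise > 0, twist > 0, twist < 360, n_total_repeats >= 4)
  structure(list(rise = rise, twist = twist,
                 n_total_repeats = n_total_repeats),
            class = "FiberBuildParams")
}

#' Build the full fiber from the 4-repeat template
#'
#' The template's four shaft repeats (C-terminal, knob-adjacent) are kept and
#' `n_total_repeats - 4` copies are propagated N-terminally: each successive
#' repeat is displaced `rise` along the fiber axis and rotated `twist` about
#' it, so the knob and the template block move up by `(n-4) * rise` while the
#' tail stays at the base. Residues are renumbered contiguously per chain.
#'
#' @param template fiber template from [make_fiber_template()].
#' @param params a `FiberBuildParams`.
#' @return `MolecularModel` of the full fiber.
#' @export
build_fiber <- function(template, params = fiber_build_params()) {
  md <- template$metadata
  if (is.null(md$repeat_start_residue) || is.null(md$beads_per_repeat)) {
    stop("template lacks repeat-frame annotation")
  }
  n <- params$n_total_repeats
  n_tpl <- md$n_template_repeats
  bpr <- md$beads_per_repeat
  rep_start <- md$repeat_start_residue
  step_tf <- rt_compose(rt_translation(c(0, 0, params$rise)),
                        rt_axis_angle(c(0, 0, 1), params$twist))
  atoms <- list(); chains <- list()
  for (cid in names(template$chains)) {
    idx <- which(template$atoms$chain_id == cid)
    a <- template$atoms[idx, , drop = FALSE]
    res <- a$residue_index
    pre <- a[res < rep_start, , drop = FALSE]                 # tail + neck
    rep1 <- a[res >= rep_start & res < rep_start + bpr, , drop = FALSE]
    knob <- a[res >= rep_start + n_tpl * bpr, , drop = FALSE]
    # repeats 1..n: screw-transform powers of the first template repeat
    rep_list <- vector("list", n)
    tf <- rt_identity()
    for (k in seq_len(n)) {
      blk <- rep1
      xyz <- rt_apply(tf, cbind(blk$x, blk$y, blk$z))
      blk$x <- xyz[, 1]; blk$y <- xyz[, 2]; blk$z <- xyz[, 3]
      blk$residue_index <- rep_start + (k - 1) * bpr + seq_len(bpr) - 1
      rep_list[[k]] <- blk
      tf <- rt_compose(step_tf, tf)
    }
    lift <- Reduce(rt_compose, rep(list(step_tf), n - n_tpl), rt_identity())
    kxyz <- rt_apply(lift, cbind(knob$x, knob$y, knob$z))
    knob$x <- kxyz[, 1]; knob$y <- kxyz[, 2]; knob$z <- kxyz[, 3]
    knob$residue_index <- rep_start + n * bpr + seq_len(nrow(knob)) - 1
    chain_atoms <- rbind(pre, do.call(rbind, rep_list), knob)
    atoms[[cid]] <- chain_atoms
    dom <- template$chains[[cid]]$domains
    dom$shaft <- c(rep_start, rep_start + n * bpr - 1)
    dom$knob <- c(rep_start + n * bpr, max(chain_atoms$residue_index))
    chains[[cid]] <- list(role = template$chains[[cid]]$role, domains = dom)
  }
  a <- do.call(rbind, atoms)
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  md$n_repeats_built <- n
  md$kind <- "fiber"
  molecular_model("fiber", a, chains, metadata = md)
}

#' Axial extent of a standalone fiber
#' @param fiber built fiber model (axis along z).
#' @return length in Angstrom from tail attachment to knob apex.
#' @export
fiber_length <- function(fiber) {
  z <- fiber$atoms$z
  max(z) - min(z)
}

# ------------------------------------------------------------- the lattice ----

# 21 triangular lattice points of the facet: 3 penton vertices, 18 hexon
# slots (12 canonical with asymmetric-unit labels, 6 edge extensions)
facet_lattice <- function(spec = fixture_spec()) {
  L <- spec$facet_edge_length
  Rv <- L / sqrt(3)
  vaz <- c(90, 210, 330) * pi / 180
  V <- cbind(Rv * cos(vaz), Rv * sin(vaz))
  pts <- list()
  # edges in cyclic order V1->V2->V3->V1; k = 1..4 along each edge
  for (e in 1:3) {
    from <- V[e, ]; to <- V[e %% 3 + 1, ]
    for (k in 1:4) {
      p <- from + (k / 5) * (to - from)
      pts[[length(pts) + 1]] <- data.frame(
        x = p[1], y = p[2], kind = "hexon",
        class = if (k <= 2) "canonical" else "extension",
        edge = e, edge_k = k, sector = e - 1, stringsAsFactors = FALSE)
    }
  }
  # interior points: i + j <= 5 grid with i, j >= 1, i + j <= 4
  e1 <- (V[2, ] - V[1, ]) / 5
  e2 <- (V[3, ] - V[1, ]) / 5
  for (i in 1:3) for (j in 1:3) {
    if (i + j > 4) next
    p <- V[1, ] + i * e1 + j * e2
    pts[[length(pts) + 1]] <- data.frame(
      x = p[1], y = p[2], kind = "hexon", class = "canonical",
      edge = NA_integer_, edge_k = NA_integer_,
      sector = NA_integer_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pts)
  # sector of interior points by azimuth: sector 0 spans the arc from V1
  # (90 deg) CCW to V2 (210 deg)
  az <- (atan2(df$y, df$x) * 180 / pi) %% 360
  int <- is.na(df$sector)
  df$sector[int] <- ((az[int] - 90) %/% 120) %% 3
  # asymmetric-unit labels within each sector:
  # 1 peripentonal edge slot (edge_k 1), 2 second edge slot (edge_k 2),
  # 3 outer interior, 4 inner interior
  df$label <- "edge"
  r <- sqrt(df$x^2 + df$y^2)
  for (s in 0:2) {
    in_s <- which(df$sector == s & df$class == "canonical")
    for (ii in in_s) {
      if (!is.na(df$edge_k[ii])) {
        df$label[ii] <- as.character(df$edge_k[ii])
      } else {
        df$label[ii] <- if (r[ii] > mean(range(r[in_s][is.na(df$edge_k[in_s])])))
          "3" else "4"
      }
    }
  }
  df$slot_index <- seq_len(nrow(df))
  df$rot_deg <- 120 * ifelse(is.na(df$sector), 0, df$sector)
  attr(df, "vertices") <- V
  df
}

#' Assemble the facet
#'
#' Places 18 hexon trimers on the triangular lattice (edge length from the
#' spec), penton pentamers at the three vertices, and a full fiber (built
#' from the template at the configured rise/twist/repeat count) along +z at
#' each vertex. Errors if any two placed components clash at default
#' parameters, naming the offending slot.
#'
#' @param hexon hexon trimer model.
#' @param penton penton base model.
#' @param fiber *either* a fiber template (built here) or a pre-built fiber.
#' @param spec a `FixtureSpec`.
#' @return object of class `FacetModel`: slot table, transforms, the merged
#'   static model, and cached marker indices.
#' @export
assemble_facet <- function(hexon = NULL, penton = NULL, fiber = NULL,
                           spec = fixture_spec()) {
  if (is.null(hexon)) hexon <- make_hexon_trimer(spec)
  if (is.null(penton)) penton <- make_penton_base(spec)
  if (is.null(fiber)) fiber <- make_fiber_template(spec)
  if (identical(fiber$metadata$kind, "fiber_template")) {
    fiber <- build_fiber(fiber, fiber_build_params(
      rise = spec$shaft_rise_per_repeat,
      twist = spec$shaft_twist_per_repeat,
      n_total_repeats = spec$n_shaft_repeats))
  }
  lat <- facet_lattice(spec)
  V <- attr(lat, "vertices")
  comp <- list(); tfs <- list()
  for (i in seq_len(nrow(lat))) {
    tf <- rt_compose(rt_translation(c(lat$x[i], lat$y[i], 0)),
                     rt_axis_angle(c(0, 0, 1), lat$rot_deg[i]))
    m <- transform_model(hexon, tf)
    m$name <- sprintf("HX%02d", lat$slot_index[i])
    comp[[m$name]] <- m
    tfs[[m$name]] <- tf
  }
  penton_fiber <- list()
  for (v in 1:3) {
    tfp <- rt_compose(rt_translation(c(V[v, 1], V[v, 2], 0)),
                      rt_axis_angle(c(0, 0, 1), 120 * (v - 1)))
    mp <- transform_model(penton, tfp)
    mp$name <- paste0("PB", v)
    comp[[mp$name]] <- mp
    tff <- rt_compose(rt_translation(c(V[v, 1], V[v, 2],
                                       spec$calib$penton$height + 1)),
                      rt_axis_angle(c(0, 0, 1), 120 * (v - 1)))
    mf <- transform_model(fiber, tff)
    mf$name <- paste0("FB", v)
    comp[[mf$name]] <- mf
    penton_fiber[[v]] <- list(vertex_index = v, xy = V[v, ],
                              penton_tf = tfp, fiber_tf = tff)
  }
  # pairwise clash check between nearby components
  nms <- names(comp)
  cen <- t(vapply(comp, model_centroid, numeric(3)))
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    if (sqrt(sum((cen[i, ] - cen[j, ])^2)) > 450) next
    if (has_clash(coords(comp[[i]]), coords(comp[[j]]),
                  comp[[i]]$atoms$vdw_radius, comp[[j]]$atoms$vdw_radius)) {
      stop("assembly clash between ", nms[i], " and ", nms[j])
    }
  }
  model <- merge_models(comp, name = "facet", prefix = TRUE)
  facet <- structure(list(
    spec = spec,
    lattice = lat,
    vertices = V,
    slot_transforms = tfs,
    penton_vertices = penton_fiber,
    model = model,
    frame = list(origin = c(0, 0, 0), normal = c(0, 0, 1)),
    hexon_top_z = hexon$metadata$top_z,
    prototype = list(hexon = hexon, penton = penton, fiber = fiber)
  ), class = "FacetModel")
  # cached selections on the merged model
  facet$hvr1_idx <- select_atoms(model, domain = "hvr1")
  canon <- sprintf("HX%02d", lat$slot_index[lat$class == "canonical"])
  pref <- sub("\\..*", "", model$atoms$chain_id[facet$hvr1_idx])
  facet$hvr1_idx_canonical <- facet$hvr1_idx[pref %in% canon]
  facet$fiber_idx <- select_atoms(model, role = "fiber")
  facet$coords <- coords(model)
  facet$radii <- model$atoms$vdw_radius
  facet
}

#' @export
print.FacetModel <- function(x, ...) {
  cat("FacetModel:", sum(x$lattice$kind == "hexon"), "hexon slots,",
      length(x$penton_vertices), "pentons/fibers,",
      n_atoms(x$model), "beads\n")
  invisible(x)
}

#' Measure the facet edge length
#'
#' Mean of the three penton-centroid to penton-centroid distances; the
#' maximum deviation among the three edges is reported as a symmetry check.
#'
#' @param facet a `FacetModel`.
#' @return list with `mean`, `edges` (length 3), `max_deviation`.
#' @export
measure_edge_length <- function(facet) {
  cen <- lapply(1:3, function(v) {
    idx <- which(facet$model$atoms$chain_id %in%
                 paste0("PB", v, ".P", 1:5))
    model_centroid(facet$model, idx)
  })
  d <- c(sqrt(sum((cen[[1]] - cen[[2]])^2)),
         sqrt(sum((cen[[2]] - cen[[3]])^2)),
         sqrt(sum((cen[[3]] - cen[[1]])^2)))
  list(mean = mean(d), edges = d, max_deviation = max(abs(d - mean(d))))
}

#' Measure a mounted fiber's length
#'
#' Axial extent (along the facet normal) from the tail attachment point to
#' the knob apex of the fiber at the given vertex.
#'
#' @param facet a `FacetModel`.
#' @param vertex_index 1, 2 or 3.
#' @return length in Angstrom.
#' @export
measure_fiber_length <- function(facet, vertex_index) {
  if (!vertex_index %in% 1:3) stop("vertex_index must be 1, 2 or 3")
  idx <- which(startsWith(facet$model$atoms$chain_id,
                          paste0("FB", vertex_index, ".")))
  z <- facet$model$atoms$z[idx]
  max(z) - min(z)
}

#' Hexon slot centres of the facet
#' @param facet a `FacetModel`.
#' @param label optional asymmetric-unit label filter ("1".."4" or "edge").
#' @return data frame of slots.
#' @export
facet_slots <- function(facet, label = NULL) {
  lat <- facet$lattice
  if (!is.null(label)) lat <- lat[lat$label %in% label, , drop = FALSE]
  lat
}

# signed in-plane feasibility: distance outside the facet triangle (0 inside)
dist_outside_triangle <- function(xy, vertices) {
  # triangle given CCW; positive distance = outside
  d <- -Inf
  for (e in 1:3) {
    a <- vertices[e, ]; b <- vertices[e %% 3 + 1, ]
    edge <- b - a
    nrm <- c(edge[2], -edge[1])          # outward for CCW order?
    nrm <- nrm / sqrt(sum(nrm^2))
    # orient outward: centroid must be on the negative side
    if (sum((c(0, 0) - a) * nrm) > 0) nrm <- -nrm
    d <- max(d, sum((xy - a) * nrm))
  }
  d
}

#' Is an in-plane point over the facet surface?
#'
#' The deposition surface includes the edge-extension hexons: a point counts
#' as on-facet when it lies within `margin` (default: hexon footprint
#' radius) of the facet triangle.
#'
#' @param facet a `FacetModel`.
#' @param xy length-2 point or n x 2 matrix.
#' @param margin allowed overhang beyond the triangle, Angstrom.
#' @return logical vector.
#' @export
on_facet <- function(facet, xy, margin = 28) {
  if (is.null(dim(xy))) xy <- matrix(xy, 1, 2)
  vapply(seq_len(nrow(xy)), function(i) {
    dist_outside_triangle(xy[i, ], facet$vertices) <= margin
  }, logical(1))
}
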