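#!/usr/bin/env Rscript
# Load FX onto every hexon trimer, then compete planar and bent IgM against
# the FX layer: which FX copies are displaced, whether the DLPSP motifs stay
# accessible, and how much deposition space remains for complement.
suppressMessages(library(adcomplement))

args <- commandArgs(TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

spec <- fixture_spec(rng_seed = seed)
kit <- make_fixture_kit(spec)
facet <- assemble_facet(kit$hexon, kit$penton, kit$fiber_template, spec)

message("placing FX on all 18 hexon trimers ...")
fx <- place_fx_all(facet, kit$fx, spec)

message("competing planar IgM ...")
planar <- compete(facet, fx, kit$igm_planar, igm_pose(1, 0, "planar"))
message("  contacts: ", planar$contacts, "; FX retained ",
        length(planar$retained_fx), ", removed ", length(planar$removed_fx))

message("competing bent IgM ...")
bent <- compete(facet, fx, kit$igm_bent, igm_pose(1, 0, "bent"))
message("  contacts: ", bent$contacts, "; FX retained ",
        length(bent$retained_fx), "; DLPSP accessible: ",
        bent$dlpsp_accessible)

message("measuring residual deposition space ...")
space_free <- residual_deposition_space(facet, list(bent$igm), kit$c3b)
space_fx <- residual_deposition_space(facet,
                                      c(list(bent$igm), bent$retained_fx),
                                      kit$c3b)
message("  C3b sites without FX: ", space_free, "; with FX: ", space_fx)

jsonlite::write_json(list(
  n_fx_placed = length(fx),
  planar = list(contacts = planar$contacts,
                retained = length(planar$retained_fx),
                removed = length(planar$removed_fx)),
  bent = list(contacts = bent$contacts,
              retained = length(bent$retained_fx),
              removed = length(bent$removed_fx),
              dlpsp_accessible = bent$dlpsp_accessible),
  deposition_space = list(without_fx = space_free, with_fx = space_fx)),
  file.path(out, "competition.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
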