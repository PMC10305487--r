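# One-call orchestration of the full analysis: fixtures -> facet assembly ->
# 16-pose enumeration -> FX competition -> vertex energetics. The analysis/
# scripts are thin drivers over these functions.

#' Run configuration
#'
#' @param spec a `FixtureSpec`.
#' @param prop a `PropagationParams`.
#' @param relax_p a `RelaxParams` for the vertex survey.
#' @param nb a `NonbondedParams`.
#' @param seed master seed; per-stage seeds derive from it deterministically.
#' @param out_dir output directory (created when writing).
#' @param stages character vector of stages to run, any of
#'   `"assembly"`, `"enumeration"`, `"competition"`, `"energetics"`.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(spec = NULL, prop = propagation_params(),
                       relax_p = relax_params(max_steps = 150),
                       nb = nonbonded_params(), seed = 1L,
                       out_dir = "results",
                       stages = c("assembly", "enumeration", "competition",
                                  "energetics")) {
  if (is.null(spec)) spec <- fixture_spec(rng_seed = seed)
  structure(list(spec = spec, prop = prop, relax_p = relax_p, nb = nb,
                 seed = as.integer(seed), out_dir = out_dir,
                 stages = stages), class = "RunConfig")
}

#' Run the full pipeline
#'
#' Executes the selected stages in order and writes per-stage outputs plus a
#' manifest JSON under `config$out_dir`. Partial failure leaves completed
#' stages' outputs intact and marks the manifest.
#'
#' @param config a `RunConfig`.
#' @param write write outputs to disk (set `FALSE` for in-memory use).
#' @return list with per-stage results and the manifest.
#' @export
run_all <- function(config = run_config(), write = TRUE) {
  t0 <- Sys.time()
  res <- list()
  manifest <- list(seed = config$seed, stages = list(),
                   spec = config$spec[setdiff(names(config$spec), "calib")])
  if (write) dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  kit <- NULL
  facet <- NULL
  step <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      NULL
    })
    if (!is.null(out)) {
      manifest$stages[[name]] <<- list(status = "ok")
      res[[name]] <<- out
    }
    invisible(out)
  }

  need_kit <- function() {
    if (is.null(kit)) {
      kit <<- make_fixture_kit(config$spec)
      facet <<- assemble_facet(kit$hexon, kit$penton, kit$fiber_template,
                               config$spec)
    }
  }

  step("assembly", function() {
    need_kit()
    el <- measure_edge_length(facet)
    out <- list(facet = facet,
                edge_length = el$mean,
                edge_max_deviation = el$max_deviation,
                fiber_length = measure_fiber_length(facet, 1),
                n_hexon_slots = nrow(facet$lattice),
                n_hexon_chains = sum(vapply(facet$model$chains,
                                            function(ch) ch$role == "hexon",
                                            logical(1))))
    if (write) {
      utils::write.csv(
        data.frame(quantity = c("edge_length", "fiber_length",
                                "n_hexon_slots", "n_hexon_chains"),
                   value = c(out$edge_length, out$fiber_length,
                             out$n_hexon_slots, out$n_hexon_chains)),
        file.path(config$out_dir, "assembly_measurements.csv"),
        row.names = FALSE)
    }
    out
  })

  step("enumeration", function() {
    need_kit()
    en <- enumerate_poses(facet, kit, config$prop)
    if (write) {
      utils::write.table(en$summary,
                         file.path(config$out_dir, "pose_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    en
  })

  step("competition", function() {
    need_kit()
    fx <- place_fx_all(facet, kit$fx, config$spec)
    planar <- compete(facet, fx, kit$igm_planar, igm_pose(1, 0, "planar"))
    bent <- compete(facet, fx, kit$igm_bent, igm_pose(1, 0, "bent"))
    space_free <- residual_deposition_space(
      facet, list(bent$igm), kit$c3b, config$prop)
    space_fx <- residual_deposition_space(
      facet, c(list(bent$igm), bent$retained_fx), kit$c3b, config$prop)
    out <- list(n_fx = length(fx), planar = planar, bent = bent,
                space_free = space_free, space_fx = space_fx)
    if (write) {
      jsonlite::write_json(list(
        n_fx_placed = length(fx),
        planar = list(contacts = planar$contacts,
                      retained = length(planar$retained_fx),
                      removed = length(planar$removed_fx)),
        bent = list(contacts = bent$contacts,
                    retained = length(bent$retained_fx),
                    removed = length(bent$removed_fx),
                    dlpsp_accessible = bent$dlpsp_accessible),
        deposition_space = list(without_fx = space_free,
                                with_fx = space_fx)),
        file.path(config$out_dir, "competition.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    out
  })

  step("energetics", function() {
    vms <- make_vertex_models(config$spec, 11)
    sv <- vertex_interaction_survey(vms, config$nb, config$relax_p)
    if (write) {
      utils::write.table(
        data.frame(pose = rownames(sv$table), round(sv$table, 2),
                   extensive = sv$extensive),
        file.path(config$out_dir, "vertex_survey.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    sv
  })

  manifest$wall_time_s <- as.numeric(Sys.time() - t0)
  if (write) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  res
}

#' Summarize a completed run
#'
#' @param run result of [run_all()] (or a run directory containing the
#'   written outputs).
#' @return character vector of summary lines, printed invisibly.
#' @export
report_summary <- function(run) {
  lines <- character()
  if (is.character(run)) {
    mf <- file.path(run, "manifest.json")
    if (!file.exists(mf)) stop("no manifest found in ", run)
    ps <- file.path(run, "pose_summary.tsv")
    summary <- if (file.exists(ps)) {
      utils::read.delim(ps, stringsAsFactors = FALSE)
    } else NULL
  } else {
    summary <- run$enumeration$summary
  }
  if (!is.null(summary)) {
    occ <- table(factor(summary$n_vertices_occupied, levels = 0:3))
    lines <- c(lines, sprintf(
      "vertices occupied: 2x%d, 1x%d, 0x%d", occ["2"], occ["1"], occ["0"]))
    lines <- c(lines, sprintf("poses with a single feasible C4b: %d",
                              sum(summary$n_c4b == 1)))
    lines <- c(lines, sprintf("total C3b bound across poses: %d",
                              sum(summary$n_c3b)))
  }
  if (!is.character(run) && !is.null(run$competition)) {
    co <- run$competition
    lines <- c(lines, sprintf(
      "FX: %d placed; planar IgM contacts %d tips, %d FX retained; bent DLPSP accessible: %s",
      co$n_fx, co$planar$contacts, length(co$planar$retained_fx),
      co$bent$dlpsp_accessible))
    lines <- c(lines, sprintf(
      "deposition space: %d sites without FX, %d with FX",
      co$space_free, co$space_fx))
  }
  if (!is.character(run) && !is.null(run$energetics)) {
    lines <- c(lines, sprintf(
      "vertex survey: %d poses, %d with extensive interactions",
      nrow(run$energetics$table), sum(run$energetics$extensive)))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
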