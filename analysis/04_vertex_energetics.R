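#!/usr/bin/env Rscript
# Vertex interaction-energy survey: 11 starting vertex models (penton base
# pentamer + trimeric fiber + one C3b nearby), relaxed by fixed-base
# steepest descent, then nonbonded interaction energies between C3b and each
# of the eight vertex chains (P1-P5, F1-F3).
suppressMessages(library(adcomplement))

args <- commandArgs(TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

spec <- fixture_spec(rng_seed = seed)
message("generating 11 vertex models ...")
vms <- make_vertex_models(spec, 11)

message("relaxing and surveying ...")
sv <- vertex_interaction_survey(vms, nonbonded_params(),
                                relax_params(max_steps = 150))
tab <- data.frame(pose = rownames(sv$table), round(sv$table, 2),
                  extensive = sv$extensive)
write.table(tab, file.path(out, "vertex_survey.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab)
message(sum(sv$extensive), " of ", nrow(tab),
        " poses show extensive interactions (>= 2 chains below -40 kcal/mol)")

# residue-pair interface for the strongest pose
i_best <- which.min(apply(sv$table, 1, min))
m <- sv$relaxed[[i_best]]
best_chain <- colnames(sv$table)[which.min(sv$table[i_best, ])]
ted <- select_atoms(m, chain = "A", domain = "thioester_domain")
other <- if (startsWith(best_chain, "P")) {
  select_atoms(m, chain = best_chain, domain = "rgd_loop")
} else {
  which(m$atoms$chain_id == best_chain)
}
rp <- residue_pair_matrix(m, ted, other)
message("pose ", i_best, " vs chain ", best_chain, ": ",
        length(rp$favorable_a), " thioester-domain residues and ",
        length(rp$favorable_b), " partner residues interact favourably ",
        "(<= -1 kcal/mol)")
write.csv(rp$favorable_pairs, file.path(out, "favorable_pairs.csv"),
          row.names = FALSE)
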