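#!/usr/bin/env Rscript
# Evaluate the two selection algorithms: sensitivity (observed-vs-imputed
# overlap of sPCAs), stability (selection-count concentration), boundary
# effect (minimum sociability of selected nonrespondents), and the overlap
# between the algorithms' sPCA sets. Also scores the imputed ensemble
# against the withheld ground truth of the synthetic cohort.

suppressMessages(library(pcanet))
out <- "results/analysis"
net <- read_network(file.path(out, "cohort", "nodes.csv"),
                    file.path(out, "cohort", "edges.csv"))
flags <- setNames(net$nodes$is_respondent, net$nodes$node_id)

results <- lapply(c(eigenvector = "eigenvector", keyplayer = "keyplayer"),
                  function(alg) read_selection(file.path(out, paste0("selection_", alg, ".json"))))

stab_rows <- list(); sens_rows <- list()
for (alg in names(results)) {
  rep_ <- evaluation_report(results[[alg]], net, k = 30)
  print(rep_)
  sens_rows[[alg]] <- cbind(algorithm = alg, rep_$sensitivity)
  stab_rows[[alg]] <- cbind(algorithm = alg, rep_$stability)
  jsonlite::write_json(unclass(rep_), file.path(out, paste0("evaluation_", alg, ".json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
}
write.csv(do.call(rbind, sens_rows), file.path(out, "sensitivity.csv"), row.names = FALSE)
write.csv(do.call(rbind, stab_rows), file.path(out, "stability.csv"), row.names = FALSE)

ov <- algorithm_overlap(lapply(results, `[[`, "spca_set"), flags)
cat(sprintf("sPCAs meeting the criterion under both algorithms: %d (%d respondents, %d nonrespondents); union %d\n",
            ov$n_intersection, ov$n_intersection_respondent,
            ov$n_intersection_nonrespondent, ov$n_union))
jsonlite::write_json(ov, file.path(out, "overlap.json"), auto_unbox = TRUE, digits = NA)

# imputation benefit against the withheld ground truth: does selecting on
# the imputed ensemble come closer to the truth-network selection than
# selecting on the observed network alone?
truth <- jsonlite::read_json(file.path(out, "cohort", "truth.json"), simplifyVector = TRUE)
hid <- truth$hidden_truth
true_net <- complete_network(net$nodes,
                             rbind(net$edges,
                                   hid[hid$present, c("source", "target")]))
true_set <- top_m(eigenvector_scores(true_net), 300)
obs_set <- results$eigenvector$observed_set
spca_set <- results$eigenvector$spca_set
cat(sprintf("eigenvector overlap with truth-network selection: observed-only %d/300, imputed sPCA %d/%d\n",
            length(intersect(obs_set, true_set)),
            length(intersect(spca_set, true_set)), length(spca_set)))
jsonlite::write_json(
  list(truth_overlap_observed = length(intersect(obs_set, true_set)),
       truth_overlap_spca = length(intersect(spca_set, true_set)),
       n_spca = length(spca_set)),
  file.path(out, "truth_benchmark.json"), auto_unbox = TRUE, digits = NA)
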