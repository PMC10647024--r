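# Condition constructors. All package errors inherit from "confstrain_error"
# so callers can trap the whole family; specific classes mirror the failure
# modes of each stage (unsupported element, ensemble too small, graph
# mismatch, ...).

cs_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "confstrain_error", "error")))
}

err_unsupported_element <- function(symbols) {
  cs_error("confstrain_unsupported_element_error",
           sprintf("element(s) not supported by this potential: %s",
                   paste(unique(symbols), collapse = ", ")),
           elements = unique(symbols))
}

err_evaluation <- function(msg) cs_error("confstrain_evaluation_error", msg)

err_insufficient_ensemble <- function(n) {
  cs_error("confstrain_insufficient_ensemble_error",
           sprintf("committee uncertainty needs >= 2 member energies, got %d", n))
}

err_shape <- function(msg) cs_error("confstrain_shape_error", msg)

err_ambiguity <- function(budget) {
  cs_error("confstrain_ambiguity_error",
           sprintf("signature-guided mapping search exceeded the node budget (%d); the graph is pathologically symmetric at this path depth - retry with a larger depth", budget))
}

err_generation <- function(ligand_id, msg) {
  cs_error("confstrain_generation_error",
           sprintf("conformer generation failed for ligand '%s': %s", ligand_id, msg),
           ligand_id = ligand_id)
}

err_molecule_mismatch <- function(ligand_id, reason) {
  cs_error("confstrain_molecule_mismatch_error",
           sprintf("ligand '%s': conformer is not the same molecule as the bound structure (%s)",
                   ligand_id, reason),
           ligand_id = ligand_id)
}

err_empty_distribution <- function() {
  cs_error("confstrain_empty_distribution_error",
           "no strain-energy values to summarize (empty input)")
}

err_parse <- function(path, line, msg) {
  cs_error("confstrain_parse_error",
           sprintf("%s: line %s: %s", path, line, msg), path = path, line = line)
}

err_bonds_unavailable <- function(path) {
  cs_error("confstrain_bonds_unavailable_error",
           sprintf("'%s' was read from xyz, which carries no connectivity; this operation needs bonds (read from mol2/sdf instead)", path))
}
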