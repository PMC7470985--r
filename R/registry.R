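#' Metabolite registry
#'
#' The registry maps each secreted metabolite to its carbon count (C atoms
#' per molecule, standard chemistry) and the intracellular precursor node it
#' overflows from on the central-metabolism network. The default registry
#' holds the eleven metabolites detected in spent culture medium of
#' glucose-grown *B. thetaiotaomicron*: the organic acid fermentation
#' products (acetate, succinate, formate, propionate, lactate) and the
#' secreted amino-acid pool (histidine, cysteine, cystine -- the Cys-Cys
#' disulfide counted as one C6 species -- glutathione, asparagine, alanine).
#'
#' @param path optional path to a registry TSV with columns `metabolite`,
#'   `carbon_count`, `network_node`, `secreted`; defaults to the packaged
#'   registry.
#' @return a `data.frame` with columns `metabolite` (character),
#'   `carbon_count` (integer), `network_node` (character), `secreted`
#'   (logical).
#' @examples
#' reg <- defaultRegistry()
#' reg[reg$metabolite == "cystine", "carbon_count"]  # 6, one molecule
#' @export
defaultRegistry <- function() {
  readRegistry(extdata("metabolite_registry.tsv"))
}

#' @rdname defaultRegistry
#' @export
readRegistry <- function(path) {
  reg <- readTsv(path)
  required <- c("metabolite", "carbon_count", "network_node", "secreted")
  missing <- setdiff(required, names(reg))
  if (length(missing))
    stop("registry lacks column(s): ", paste(missing, collapse = ", "))
  reg$carbon_count <- as.integer(reg$carbon_count)
  reg$secreted <- as.logical(reg$secreted)
  validateRegistry(reg)
  reg[required]
}

validateRegistry <- function(reg) {
  if (anyDuplicated(reg$metabolite))
    stop("duplicate metabolite in registry")
  if (any(is.na(reg$carbon_count)) || any(reg$carbon_count < 1L))
    stop("carbon_count must be a positive integer for every metabolite")
  invisible(reg)
}

#' Carbon counts for a set of metabolites
#'
#' @param metabolites character vector of metabolite names.
#' @param registry a registry `data.frame` (see [defaultRegistry()]).
#' @return named integer vector of carbon counts.
#' @export
carbonCounts <- function(metabolites, registry = defaultRegistry()) {
  idx <- match(metabolites, registry$metabolite)
  if (anyNA(idx))
    stop("unregistered metabolite(s): ",
         paste(metabolites[is.na(idx)], collapse = ", "))
  stats::setNames(registry$carbon_count[idx], metabolites)
}

#' Intracellular network topology
#'
#' The fixed node set of the secretion network (glucose, pyruvate,
#' acetyl-CoA, oxaloacetate/aspartate, succinyl-CoA, the serine-cycle node
#' and the purine node) and the backbone edges between them. Secreted
#' metabolites attach to their precursor node via the registry's
#' `network_node` column. Shipped as a plain TSV so users can edit the
#' topology.
#'
#' @param path optional path to a topology TSV with columns `from`, `to`;
#'   defaults to the packaged topology.
#' @return a `data.frame` of directed backbone edges.
#' @export
defaultTopology <- function(path = extdata("network_topology.tsv")) {
  topo <- readTsv(path)
  if (!all(c("from", "to") %in% names(topo)))
    stop("topology file needs columns 'from' and 'to'")
  topo
}
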