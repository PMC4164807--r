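# End-to-end orchestration: alignment -> tree -> partition -> trace ->
# structure mapping -> binding-site report. Stages communicate via files
# under the output directory so each is independently inspectable.

#' Pipeline configuration
#'
#' Collects every input path and parameter of an end-to-end run. Defaults
#' follow the worked example's protocol: 5.0 A binding-site cutoff, >80%
#' identity selection, chain A.
#'
#' @param msa Path to the multiple sequence alignment.
#' @param msa_format `"fasta"` or `"clustal"`.
#' @param out_dir Output directory (created if absent).
#' @param query_ids Character vector: one alignment record id per
#'   structure, in the order of `pdbs` (the first is also used for the ET
#'   summary when no structure is given).
#' @param offsets Integer vector, same length as `query_ids`: first
#'   residue number of each query in its structure's numbering.
#' @param pdbs Optional named character vector of PDB paths (names are
#'   used in output filenames).
#' @param chains Chain id per structure (default `"A"`, recycled).
#' @param ligand_chains,ligand_resnames Optional per-structure ligand
#'   overrides (see [ligand_selection()]); `NA` entries use the default
#'   HETATM rule.
#' @param cutoff Binding-site cutoff in Angstrom (default 5.0).
#' @param identity_threshold Selection threshold in percent (default 80;
#'   recorded in the config echo, applied only when candidate selection is
#'   run separately).
#' @param flap_ranges Optional list of `c(start, end)` per structure.
#' @param cut_edge Optional edge id for the tree partition; `NULL` selects
#'   the deepest split automatically ([auto_partition()]).
#' @param seed Integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(msa, out_dir, query_ids, offsets = 1L,
                            msa_format = c("fasta", "clustal"),
                            pdbs = NULL, chains = "A",
                            ligand_chains = NA, ligand_resnames = NA,
                            cutoff = 5.0, identity_threshold = 80,
                            flap_ranges = NULL, cut_edge = NULL, seed = 1L) {
  msa_format <- match.arg(msa_format)
  nq <- length(query_ids)
  structure(list(msa = msa, msa_format = msa_format, out_dir = out_dir,
                 query_ids = query_ids,
                 offsets = rep_len(as.integer(offsets), nq),
                 pdbs = pdbs, chains = rep_len(chains, max(1L, length(pdbs))),
                 ligand_chains = rep_len(ligand_chains, max(1L, length(pdbs))),
                 ligand_resnames = rep_len(ligand_resnames,
                                           max(1L, length(pdbs))),
                 cutoff = cutoff, identity_threshold = identity_threshold,
                 flap_ranges = flap_ranges, cut_edge = cut_edge,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(verbose, ...) {
  if (verbose) message("[etrace] ", ...)
}

#' Run the full evolutionary trace pipeline
#'
#' Reads the alignment, builds the neighbor-joining tree, partitions it
#' into two groups, classifies columns, maps statuses onto each query,
#' and — for each supplied structure — extracts and annotates the
#' ligand-binding site, intersects it with the flap range, writes a
#' B-factor-annotated PDB, and superposes the first two structures.
#' Every output is written under `config$out_dir` together with a
#' `MANIFEST.tsv` of md5 content hashes and an echo of the effective
#' configuration. Runs are deterministic: the same config and inputs give
#' byte-identical outputs.
#'
#' Missing structure files degrade gracefully: sequence-level outputs are
#' still produced and the summary's `complete` flag is `FALSE`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log each stage to standard error (default `TRUE`).
#' @return Invisibly, a summary list: status fractions per query,
#'   binding-site tables, flap intersections, superposition RMSD and pair
#'   count, output paths, and the `complete` flag.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  produced <- character(0)
  emit <- function(p) { produced <<- c(produced, p); p }
  summary <- list(complete = TRUE)

  # config echo
  cfg <- config[!vapply(config, is.null, TRUE)]
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v) paste(format(v), collapse = ","), "")),
             emit(out("config.txt")))

  .log_stage(verbose, "reading alignment ", config$msa)
  msa <- read_alignment(config$msa, config$msa_format)

  .log_stage(verbose, "p-distance matrix and neighbor-joining tree")
  dm <- p_distance_matrix(msa)
  tree <- neighbor_joining(dm)
  ape::write.tree(tree, emit(out("tree.nwk")))

  .log_stage(verbose, "partitioning tree into two groups")
  part <- if (is.null(config$cut_edge)) auto_partition(tree, 2) else
    partition_at_edge(tree, config$cut_edge)
  write_partition(part, emit(out("partition.tsv")))

  .log_stage(verbose, "group consensus and column classification")
  cons <- lapply(sort(unique(part$groups)), function(g)
    group_consensus(msa, part, g))
  trace <- classify_columns(cons)
  write_et_sequence(trace, emit(out("et_sequence.fasta")))

  maps <- list()
  for (qi in seq_along(config$query_ids)) {
    qid <- config$query_ids[qi]
    .log_stage(verbose, "mapping statuses onto query ", qid,
               " (offset ", config$offsets[qi], ")")
    map <- map_to_query(trace, msa, qid, config$offsets[qi])
    maps[[qid]] <- map
    write_status_map(map, emit(out(paste0("status_map_", qid, ".tsv"))))
  }
  summary$status_fractions <- lapply(maps, status_fractions)

  # structural stages
  summary$binding_sites <- list()
  structures <- list()
  if (!is.null(config$pdbs)) {
    nm <- names(config$pdbs)
    if (is.null(nm)) nm <- paste0("structure", seq_along(config$pdbs))
    for (si in seq_along(config$pdbs)) {
      pdb_path <- config$pdbs[si]
      if (!file.exists(pdb_path)) {
        warning("structure file missing, skipping structural stage: ", pdb_path)
        summary$complete <- FALSE
        next
      }
      .log_stage(verbose, "structure ", nm[si], ": binding site at ",
                 config$cutoff, " A")
      s <- read_pdb(pdb_path)
      lig <- ligand_selection(
        s,
        chain = if (!is.na(config$ligand_chains[si])) config$ligand_chains[si],
        resnames = if (!is.na(config$ligand_resnames[si]))
          config$ligand_resnames[si])
      chain <- select_chain(s, config$chains[si])
      site <- binding_site(chain, lig, config$cutoff)
      qid <- config$query_ids[min(si, length(config$query_ids))]
      ann <- annotate_binding_site(site, maps[[qid]])
      utils::write.table(ann, emit(out(paste0("bindsite_", nm[si], ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$binding_sites[[nm[si]]] <- ann
      if (!is.null(config$flap_ranges) && si <= length(config$flap_ranges)) {
        fr <- config$flap_ranges[[si]]
        summary$flap[[nm[si]]] <- flap_intersection(site, fr[1], fr[2])
      }
      write_annotated_pdb(chain, maps[[qid]],
                          emit(out(paste0("annotated_", nm[si], ".pdb"))))
      structures[[nm[si]]] <- chain
    }
    if (length(structures) >= 2L) {
      .log_stage(verbose, "superposing ", nm[1], " onto ", nm[2])
      sp <- superpose_chains(structures[[1]], structures[[2]])
      utils::write.table(
        data.frame(structure_a = nm[1], structure_b = nm[2],
                   rmsd = sp$rmsd, n_pairs = sp$n_pairs),
        emit(out("superposition.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      summary$superposition <- sp
    }
  }

  manifest <- data.frame(file = basename(produced),
                         md5 = unname(tools::md5sum(produced)),
                         complete = summary$complete)
  utils::write.table(manifest, out("MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$outputs <- produced
  summary$trace <- trace
  invisible(summary)
}
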