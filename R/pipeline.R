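# End-to-end orchestration: file in, report files out.  These functions are
# the package's batch interface; each run writes a machine-readable
# provenance record (inputs, configuration, package version) next to its
# reports.

.write_provenance <- function(out_dir, inputs, config) {
  prov <- list(
    package = "prfscan",
    version = as.character(utils::packageVersion("prfscan")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = inputs,
    config = config
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.flatten_sites <- function(report) {
  if (nrow(report) == 0) {
    return(select(report, -dplyr::any_of(c("p_classes", "a_classes",
                                           "structure"))))
  }
  report %>%
    mutate(
      p_classes = vapply(.data$p_classes, paste, character(1),
                         collapse = ","),
      a_classes = vapply(.data$a_classes, paste, character(1),
                         collapse = ",")
    ) %>%
    select(-dplyr::any_of("structure"))
}

#' Scan a FASTA file for frameshift cassettes and write reports
#'
#' Runs [scan_cassette()] on every record, joins ORF-pair and fusion-product
#' predictions, and writes `cassettes.tsv`, `cassettes.json` and
#' `provenance.json` into `out_dir`.  An input without detectable sites
#' produces an empty (but valid) report; a missing or unparseable input is an
#' error.
#'
#' @param input Path to a FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param mode,shift Passed to [scan_cassette()].
#' @param bounds Structure-search bounds.
#' @param min_aa5,min_aa3 ORF-pair thresholds for the fusion report.
#' @return The combined report tibble, invisibly.
#' @export
run_scan <- function(input, out_dir, mode = "relaxed", shift = -1L,
                     bounds = structure_bounds(), min_aa5 = 10L,
                     min_aa3 = 10L) {
  seqs <- read_fasta(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- scan_cassette(seqs, mode = mode, shift = shift, bounds = bounds)
  fusions <- purrr::map_dfr(seq_len(nrow(report)), function(k) {
    site <- report[k, ]
    seq <- seqs$seq[seqs$id == site$id][1]
    pairs <- find_orf_pairs(seq, min_aa5 = min_aa5, min_aa3 = min_aa3)
    pairs <- pairs[pairs$shift == site$shift &
                     pairs$overlap_start < site$start + 7L &
                     pairs$overlap_end >= site$start + 7L, ]
    if (nrow(pairs) == 0) {
      return(tibble(id = site$id, start = site$start,
                    fusion_aa = NA_character_, fusion_mass_da = NA_real_))
    }
    fus <- tryCatch(build_fusion(seq, pairs[1, ], site),
                    error = function(e) NULL)
    if (is.null(fus)) {
      return(tibble(id = site$id, start = site$start,
                    fusion_aa = NA_character_, fusion_mass_da = NA_real_))
    }
    tibble(id = site$id, start = site$start, fusion_aa = fus$aa_seq,
           fusion_mass_da = fus$mass_da)
  })
  flat <- .flatten_sites(report)
  if (nrow(fusions) > 0) {
    flat <- left_join(flat, fusions, by = c("id", "start"))
  }
  utils::write.table(flat, file.path(out_dir, "cassettes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(flat, file.path(out_dir, "cassettes.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_provenance(out_dir, list(fasta = input),
                    list(mode = mode, shift = shift,
                         bounds = unclass(bounds), min_aa5 = min_aa5,
                         min_aa3 = min_aa3))
  invisible(flat)
}

#' Conservation and parsimony reports for an aligned cassette family
#'
#' Reads an aligned FASTA, a Newick tree and a two-column states TSV, runs
#' the base-pair conservation statistics and compensatory-change calls
#' against the reference row's predicted structure, maps the 3'-ORF character
#' with Fitch parsimony, and writes `column_stats.tsv`, `compensatory.tsv`,
#' `events.tsv`, an annotated Newick (`states_tree.nwk`, node labels carry
#' the reconstructed states) and `provenance.json`.
#'
#' @param aln_fasta Aligned FASTA (gaps as `-`).
#' @param tree_file Newick tree.
#' @param states_file TSV with columns `species`, `state`.
#' @param out_dir Output directory.
#' @param ref Reference row id (default: first record).
#' @param bounds Structure-search bounds for the reference fold.
#' @return List with the three report tibbles, invisibly.
#' @export
run_conserve <- function(aln_fasta, tree_file, states_file, out_dir,
                         ref = NULL, bounds = structure_bounds()) {
  aln <- as_cassette_alignment(read_fasta(aln_fasta))
  tree <- ape::read.tree(tree_file)
  states <- as_tibble(utils::read.delim(states_file,
                                        stringsAsFactors = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ref)) ref <- aln$id[1]
  ref_seq <- gsub("-", "", aln$seq[aln$id == ref], fixed = TRUE)
  sites <- scan_slippery(ref_seq)
  comp <- tibble()
  stats_tab <- tibble()
  if (nrow(sites) > 0) {
    folds <- fold_downstream(ref_seq, sites[1, ], bounds)
    best <- if (!is.null(folds$pseudoknot)) folds$pseudoknot else
      folds$hairpin
    if (!is.null(best)) {
      proj <- project_structure(aln, ref, best)
      stats_tab <- column_pair_stats(aln, proj$col5, proj$col3) %>%
        mutate(stem = proj$stem, .before = 1)
      comp <- find_compensatory(aln, ref, best)
    }
  }
  fit <- fitch_map(tree, states)
  events <- tidy(fit)
  utils::write.table(stats_tab, file.path(out_dir, "column_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comp, file.path(out_dir, "compensatory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- fit$tree
  ntip <- length(tr$tip.label)
  tr$node.label <- fit$node_states[(ntip + 1):(ntip + tr$Nnode)]
  ape::write.tree(tr, file.path(out_dir, "states_tree.nwk"))
  .write_provenance(out_dir,
                    list(alignment = aln_fasta, tree = tree_file,
                         states = states_file),
                    list(ref = ref, bounds = unclass(bounds)))
  invisible(list(column_stats = stats_tab, compensatory = comp,
                 events = events))
}

#' Quantify frameshifting efficiencies from a reporter TSV
#'
#' Reads the measurements, fits per-construct efficiencies against the named
#' control ([reporter_fit()]), and writes `efficiency.tsv`,
#' `efficiency.json` and `provenance.json`.
#'
#' @param input TSV with columns `construct`, `replicate`, `beta_gal`,
#'   `luciferase`.
#' @param control Name of the in-frame control construct (required).
#' @param out_dir Output directory.
#' @return The [reporter_fit()] object, invisibly.
#' @export
run_quant <- function(input, control, out_dir) {
  if (missing(control)) {
    abort("`control` is required: name the in-frame control construct")
  }
  data <- read_reporter(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- reporter_fit(data, control)
  est <- tidy(fit)
  utils::write.table(est, file.path(out_dir, "efficiency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(est, file.path(out_dir, "efficiency.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_provenance(out_dir, list(reporter = input), list(control = control))
  invisible(fit)
}

#' Plot base-pair conservation along a reference structure
#'
#' Tile plot of the paired columns of the reference structure: fill encodes
#' the number of distinct compatible pair types (sequence covariation), the
#' border the count of incompatible rows (structure disruption).
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param ref Reference row id.
#' @param structure `prf_pseudoknot`/`prf_stem` on the reference row.
#' @return A ggplot.
#' @export
plot_pair_conservation <- function(aln, ref, structure) {
  proj <- project_structure(aln, ref, structure)
  stats_tab <- column_pair_stats(aln, proj$col5, proj$col3) %>%
    mutate(stem = factor(proj$stem),
           pair = dplyr::row_number())
  ggplot2::ggplot(stats_tab,
                  ggplot2::aes(x = .data$pair, y = .data$stem,
                               fill = .data$n_pair_types)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$n_incompatible),
                       linewidth = 0.8, width = 0.9, height = 0.9) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 6)) +
    ggplot2::scale_colour_gradient(low = "white", high = "red") +
    ggplot2::labs(x = "Base pair (5' to 3' along stem)", y = "Stem",
                  fill = "Pair types", colour = "Incompatible rows") +
    ggplot2::theme_minimal()
}

#' Arc diagram of a predicted structure
#'
#' @param object A `prf_pseudoknot`.
#' @param ... Unused.
#' @return A ggplot arc diagram (stem 1 above, stem 2 below the sequence
#'   line).
#' @export
autoplot.prf_pseudoknot <- function(object, ...) {
  pairs <- tidy(object)
  arcs <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    x0 <- pairs$pos5[k]
    x1 <- pairs$pos3[k]
    t <- seq(0, pi, length.out = 40)
    tibble(
      pair = k, stem = pairs$stem[k],
      x = (x0 + x1) / 2 + (x1 - x0) / 2 * cos(t),
      y = (if (pairs$stem[k] == 1) 1 else -1) * (x1 - x0) / 2 * sin(t)
    )
  })
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$pair,
                                     colour = factor(.data$stem))) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`1` = "#1b9e77",
                                            `2` = "#d95f02")) +
    ggplot2::labs(x = "Position (0-based)", y = NULL, colour = "Stem") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
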