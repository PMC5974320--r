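# End-to-end orchestration: simulate (or ingest) -> normalize -> classify ->
# homoeologue comparison -> k-mer screen -> motif scan -> motif clustering,
# with a machine-readable run report. Stages run sequentially and abort with
# the failing stage's name.

default_scan_motifs <- function(config) {
  motif_set(
    motif_from_iupac("planted", config$plant_motif, source_tag = "simulation"),
    motif_from_iupac("E2", "[TA][TC]CAC", source_tag = "literature"),
    motif_from_iupac("VM1", "[TC][TC]TCT", source_tag = "literature")
  )
}

#' Run the full localization analysis pipeline on a synthetic study
#'
#' Executes simulate, normalize (anchor size factors + expression filter),
#' classify (RNA consensus profiles and per-replicate protein quorum),
#' homoeologue concordance and motif counts, k-mer over-representation
#' (animal group = extremely animal UTRs; vegetal group = vegetal plus
#' extremely vegetal), motif presence scanning with Fisher enrichment, and
#' motif family clustering.
#'
#' @param config `synth_config` describing the study.
#' @param motifs motif set used for scanning/clustering (default: the
#'   planted element plus two classical CAC-rich/UC-rich consensus motifs).
#' @param k k-mer length for the over-representation screen.
#' @param expression_threshold minimum mean normalized read.
#' @param alpha significance level for k-mer and scan statistics.
#' @param out_dir optional directory; when given, all result tables are
#'   written as TSV (plus a JSON run summary and a newick dendrogram).
#' @return list of class `tomoloc_report` with per-stage results and counts.
#' @export
run_pipeline <- function(config = synth_config(), motifs = NULL, k = 5,
                         expression_threshold = 15, alpha = 0.001,
                         out_dir = NULL) {
  motifs <- motifs %||% default_scan_motifs(config)
  report <- list(seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- stage("simulate", simulate_dataset(config))
  report$stages$simulate <- list(
    n_genes = nrow(sim$truth), n_pairs = if (is.null(sim$pairs)) 0L else nrow(sim$pairs),
    n_utrs = nrow(sim$utrs))

  norm <- stage("normalize", {
    sf <- compute_size_factors(sim$counts, sim$cq)
    normalized <- apply_size_factors(sim$counts, sf) |>
      filter_low_expression(expression_threshold)
    fr <- to_fractions(normalized)
    list(size_factors = sf, normalized = normalized,
         fractions = fr, consensus = consensus_fractions(fr))
  })
  report$stages$normalize <- list(
    n_genes_kept = dplyr::n_distinct(norm$normalized$gene_id),
    n_genes_removed = dplyr::n_distinct(sim$counts$gene_id) -
      dplyr::n_distinct(norm$normalized$gene_id))

  cls <- stage("classify", {
    labels <- classify_rna(norm$consensus)
    prot_fr <- to_fractions(global_mean_normalize(sim$protein$intensities))
    prot_labels <- classify_replicates(prot_fr, "protein")
    list(rna = labels, rna_summary = summarize_categories(labels, "rna"),
         protein = prot_labels,
         protein_summary = summarize_categories(prot_labels, "protein"))
  })
  report$stages$classify <- list(
    rna_proportions = setNames(cls$rna_summary$proportion,
                               as.character(cls$rna_summary$category)),
    n_proteins = nrow(cls$protein))

  hom <- stage("homoeolog", {
    pairing <- pair_homoeologs(cls$rna$gene_id)
    conc <- concordance(pairing$pairs, cls$rna)
    counts <- pair_motif_counts(head(conc$pairs[!conc$pairs$concordant, ], 50),
                                sim$utrs, motifs[1, ])
    list(pairing = pairing, concordance = conc, discordant_motif_counts = counts)
  })
  report$stages$homoeolog <- list(
    n_pairs = hom$concordance$n_pairs,
    fraction_concordant = hom$concordance$fraction_concordant)

  km <- stage("kmers", {
    by_cat <- split(cls$rna$gene_id, cls$rna$category)
    animal_utrs <- filter(sim$utrs, .data$gene_id %in% by_cat$extremely_animal)
    vegetal_utrs <- filter(sim$utrs, .data$gene_id %in%
                             c(by_cat$vegetal, by_cat$extremely_vegetal))
    a <- overrepresented_kmers(animal_utrs, k, alpha)
    v <- overrepresented_kmers(vegetal_utrs, k, alpha)
    uq <- unique_kmers(a, v)
    xr <- crossref_motifs(uq$kmer, motifs)
    list(animal = a, vegetal = v, unique = uq, crossref = xr)
  })
  report$stages$kmers <- list(
    n_significant_animal = sum(km$animal$significant),
    n_significant_vegetal = sum(km$vegetal$significant),
    n_unique = nrow(km$unique))

  sc <- stage("scan", {
    pres <- presence_summary(sim$utrs, cls$rna, motifs)
    veg <- filter(pres, .data$motif_id == motifs$motif_id[1],
                  .data$category %in% c("vegetal", "extremely_vegetal"))
    ctrl <- filter(pres, .data$motif_id == motifs$motif_id[1],
                   .data$category == "extremely_animal")
    enr <- if (nrow(veg) && nrow(ctrl)) {
      fisher_enrichment(sum(veg$n_with_hit), sum(veg$n_genes) - sum(veg$n_with_hit),
                        sum(ctrl$n_with_hit), sum(ctrl$n_genes) - sum(ctrl$n_with_hit))
    } else NULL
    list(presence = pres, enrichment = enr)
  })
  report$stages$scan <- list(n_rows = nrow(sc$presence))

  cl <- stage("cluster", {
    d <- motif_distance_matrix(motifs, min_overlap = min(4, min(motifs$width)))
    tree <- upgma(d)
    fams <- cut_families(tree, motifs, height = 0.25)
    list(distance = d, tree = tree, families = fams)
  })
  report$stages$cluster <- list(n_families = nrow(cl$families))

  result <- structure(list(
    report = report, simulation = sim, normalization = norm,
    classification = cls, homoeolog = hom, kmers = km, scan = sc,
    cluster = cl), class = "tomoloc_report")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_segment_table(result$normalization$normalized, p("normalized_counts.tsv"))
  readr::write_tsv(result$normalization$size_factors, p("size_factors.tsv"))
  readr::write_tsv(result$normalization$fractions, p("fractions.tsv"))
  readr::write_tsv(result$classification$rna, p("rna_labels.tsv"))
  readr::write_tsv(result$classification$rna_summary, p("rna_summary.tsv"))
  readr::write_tsv(result$classification$protein, p("protein_labels.tsv"))
  readr::write_tsv(result$kmers$vegetal, p("kmers_vegetal.tsv"))
  readr::write_tsv(result$kmers$animal, p("kmers_animal.tsv"))
  readr::write_tsv(result$kmers$unique, p("kmers_unique.tsv"))
  readr::write_tsv(result$scan$presence, p("motif_presence.tsv"))
  readr::write_tsv(result$homoeolog$concordance$pairs, p("homoeolog_pairs.tsv"))
  readr::write_tsv(select(result$cluster$families, -"pwm", -"members"),
                   p("motif_families.tsv"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(result$cluster$tree, p("motif_dendrogram.nwk"))
  }
  jsonlite::write_json(result$report, p("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.tomoloc_report <- function(x, ...) {
  r <- x$report
  cat("tomoloc pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  simulate: %d genes, %d homoeologue pairs, %d UTRs\n",
              r$stages$simulate$n_genes, r$stages$simulate$n_pairs,
              r$stages$simulate$n_utrs))
  cat(sprintf("  normalize: %d genes kept (%d below expression threshold)\n",
              r$stages$normalize$n_genes_kept, r$stages$normalize$n_genes_removed))
  props <- r$stages$classify$rna_proportions
  cat("  classify: ", paste(sprintf("%s %.1f%%", names(props), 100 * props),
                            collapse = ", "), "\n", sep = "")
  cat(sprintf("  homoeolog: %.1f%% concordant of %d pairs\n",
              100 * r$stages$homoeolog$fraction_concordant,
              r$stages$homoeolog$n_pairs))
  cat(sprintf("  kmers: %d significant animal, %d vegetal, %d unique\n",
              r$stages$kmers$n_significant_animal,
              r$stages$kmers$n_significant_vegetal, r$stages$kmers$n_unique))
  cat(sprintf("  cluster: %d motif families\n", r$stages$cluster$n_families))
  invisible(x)
}
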