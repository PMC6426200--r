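# One-call orchestration: haplotype -> assign -> dedup -> diversity /
# Fisher scan / FST + MDS / admixture / network dating, from a single
# config, with a run manifest for reproducibility.  Stages are skippable
# so frequency-only datasets (no sequences) run the statistical stages
# alone.

#' Run the full analysis pipeline
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized fields:
#'   \describe{
#'     \item{out_dir}{Output directory (required; created).}
#'     \item{seed}{Integer seed recorded in the manifest and used by all
#'       stochastic stages.}
#'     \item{freq_table}{Path of a haplogroup frequency TSV.  When
#'       absent but sequences are given, frequencies are computed from
#'       the assigned samples.}
#'     \item{fasta, sample_table, phylotree, reference}{Paths for the
#'       haplotyping stages; `reference` is a FASTA whose single record
#'       is the reference segment, with `reference_start` giving its
#'       1-based coordinate (default 16000).}
#'     \item{east, west}{Population labels for the asymmetry scan
#'       (defaults as in [asymmetry_scan()]).}
#'     \item{exclude_west}{Optional labels removed from `west` for a
#'       second, reduced scan.}
#'     \item{clock_rate}{Years per substitution, default 3624.}
#'     \item{epsilon}{Median-joining tolerance, default 0.}
#'     \item{bootstrap_B}{Admixture bootstrap replicates, default 200.}
#'     \item{admixture}{List with `hybrid` (counts named by category) or
#'       `hybrid_population` (column of the frequency table) and
#'       `parental_populations` (columns).}
#'     \item{dating}{List with `haplogroup` (clade label to date from
#'       the assigned samples).}
#'     \item{stages}{Character vector to restrict which stages run.}
#'   }
#' @return Named list of stage results (also written under `out_dir`
#'   with a `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  for (f in c("freq_table", "fasta", "sample_table", "phylotree",
              "reference")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file for ", sQuote(f), " not found: ", cfg[[f]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stages <- cfg$stages %||% c("haplotype", "diversity", "fisher", "fst",
                              "mds", "admixture", "dating")
  rate <- rate_config(cfg$clock_rate %||% 3624)
  epsilon <- cfg$epsilon %||% 0
  out <- list()
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE))
  }
  samples <- NULL
  tree <- if (!is.null(cfg$phylotree)) read_phylotree(cfg$phylotree)
  segment <- NULL
  if (!is.null(cfg$reference)) {
    refseq <- read_fasta(cfg$reference)
    segment <- ref_segment(names(refseq)[1], refseq[[1]],
                           start = cfg$reference_start %||% 16000L)
  }
  # --- haplotyping ------------------------------------------------------
  if ("haplotype" %in% stages && !is.null(cfg$fasta)) {
    samples <- step("haplotype", {
      if (is.null(segment)) stop("haplotyping needs a reference")
      if (is.null(tree)) stop("haplotyping needs a phylotree")
      seqs <- read_fasta(cfg$fasta)
      smp <- if (!is.null(cfg$sample_table))
        read_sample_table(cfg$sample_table)
      else data.frame(sample_id = names(seqs), island = "other",
                      site = "", period = "ancient", haplogroup = "",
                      motif = "", multiplicity = 1L,
                      stringsAsFactors = FALSE)
      calls <- lapply(seqs, function(s)
        call_variants(align_to_reference(s, segment)))
      m <- match(smp$sample_id, names(seqs))
      smp$motif <- vapply(calls[m], function(x) format(x$motif), "")
      smp$haplogroup <- vapply(calls[m], function(x)
        assign_haplogroup(x$motif, tree, segment)$haplogroup, "")
      smp
    })
    emit("assigned_samples.tsv",
         function(p) write_sample_table(samples, p))
    out$samples <- samples
  }
  # --- frequency table --------------------------------------------------
  freqs <- step("frequencies", {
    if (!is.null(cfg$freq_table)) read_freq_table(cfg$freq_table)
    else if (!is.null(samples))
      haplogroup_frequencies(dedup_by_site(samples, "population-analysis"),
                             pool_lanfue = isTRUE(cfg$pool_lanfue))
    else stop("no frequency table and no samples to build one from")
  })
  out$frequencies <- freqs
  emit("frequencies.tsv", function(p) write_freq_table(freqs, p))
  # --- diversity --------------------------------------------------------
  if ("diversity" %in% stages) {
    out$diversity <- step("diversity", {
      res <- lapply(colnames(freqs), function(pop) {
        d <- nei_diversity(unclass(freqs)[, pop])
        data.frame(population = pop, H = d$H, SE = d$SE, n = d$n, k = d$k)
      })
      do.call(rbind, res)
    })
    emit("diversity.tsv", function(p)
      utils::write.table(out$diversity, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }
  # --- Fisher asymmetry scan -------------------------------------------
  if ("fisher" %in% stages) {
    east <- cfg$east %||% c("GCA", "LAN&FUE")
    west <- cfg$west %||% c("HIE", "PAL", "TFE", "GOM")
    out$fisher <- step("fisher", asymmetry_scan(freqs, east, west))
    emit("fisher_scan.tsv", function(p)
      utils::write.table(out$fisher, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    if (!is.null(cfg$exclude_west)) {
      out$fisher_reduced <- step("fisher",
        asymmetry_scan(freqs, east, setdiff(west, cfg$exclude_west)))
      emit("fisher_scan_reduced.tsv", function(p)
        utils::write.table(out$fisher_reduced, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
  }
  # --- distances + MDS --------------------------------------------------
  if ("fst" %in% stages && ncol(freqs) >= 2) {
    out$distances <- step("fst", distance_matrix(freqs))
    emit("distances.tsv", function(p)
      utils::write.table(data.frame(population = rownames(out$distances),
                                    unclass(out$distances),
                                    check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if ("mds" %in% stages && !is.null(out$distances) &&
      nrow(out$distances) > 2) {
    out$mds <- step("mds", smacof_mds(out$distances, dims = 2, seed = seed))
    emit("mds_coordinates.tsv", function(p)
      utils::write.table(data.frame(population = rownames(out$mds$coordinates),
                                    out$mds$coordinates),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  # --- admixture --------------------------------------------------------
  if ("admixture" %in% stages && !is.null(cfg$admixture)) {
    out$admixture <- step("admixture", {
      a <- cfg$admixture
      hybrid <- if (!is.null(a[["hybrid"]])) unlist(a[["hybrid"]]) else
        unclass(freqs)[, a$hybrid_population]
      parentals <- lapply(a$parental_populations, function(pp)
        unclass(freqs)[, pp])
      names(parentals) <- unlist(a$parental_populations)
      bootstrap_admixture(hybrid, parentals,
                          B = cfg$bootstrap_B %||% 200, seed = seed)
    })
    emit("admixture.tsv", function(p)
      utils::write.table(data.frame(parental = names(out$admixture$m),
                                    m = out$admixture$m,
                                    SE = out$admixture$SE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  # --- clade dating -----------------------------------------------------
  if ("dating" %in% stages && !is.null(cfg$dating) && !is.null(samples)) {
    out$dating <- step("dating", {
      res <- date_clade(samples, cfg$dating$haplogroup, tree, rate,
                        segment = segment, epsilon = epsilon)
      net <- attr(res, "network")
      emit("clade_network.json", function(p) write_network(net, p, "json"))
      res
    })
    emit("dating.json", function(p)
      jsonlite::write_json(out$dating[c("rho", "sigma", "n", "age_years",
                                        "age_SE_years", "low_information")],
                           p, auto_unbox = TRUE, digits = NA))
  }
  emit("manifest.json", function(p)
    write_manifest(p, params = c(cfg[setdiff(names(cfg), "admixture")],
                                 list(seed = seed)),
                   outputs = outputs))
  invisible(out)
}
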