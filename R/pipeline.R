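## Pipeline orchestration: one configuration in, a directory of auditable
## tables out.

#' Default pipeline configuration
#'
#' @return A named list of defaults; see [run_hri_pipeline()] for the
#'   meaning of each entry.
#' @export
default_config <- function() {
  list(
    input = "simulate",            # or "files"
    sim = list(),                  # overrides for sim_params()
    paths = list(),                # fixture_dir for input = "files"
    n_chromosomes = 128L,
    n_bins = 45L,
    grid_size = 200L,
    rr_threshold = 2,
    rr_threshold_high = 5,
    span = 1.0,
    clamp = TRUE,
    split_parts = 3L,
    use_split_part = 2L,           # part used for Ka+ estimation
    bootstrap_B = 0L,
    seed = 1L,
    core_margin_codons = 8L,
    stages = c("counts", "analysis"),
    out_dir = "hri_out")
}

serialize_sfs <- function(mat) apply(mat, 1, paste, collapse = ",")

#' Run the full interference pipeline from a configuration
#'
#' Loads or simulates the gene set, splits 4-fold divergence into
#' independent parts, runs the recombination-bin DFE analysis and the loss
#' estimate, optionally bootstraps, and writes all tables plus a manifest
#' to the output directory. Reruns with the same configuration and seed are
#' bit-identical for the deterministic stages.
#'
#' @param config A list (merged over [default_config()]) or the path to a
#'   YAML file with the same structure. Keys: `input` ("simulate" or
#'   "files"), `sim` (overrides for [sim_params()]), `paths$fixture_dir`
#'   (for file input), `n_chromosomes`, `n_bins`, `grid_size`,
#'   `rr_threshold`, `span`, `clamp`, `split_parts`, `use_split_part`,
#'   `bootstrap_B`, `seed`, `core_margin_codons`, `stages` (any of
#'   `"counts"`, `"analysis"`), `out_dir`.
#' @return Invisibly, a list with the gene set, the [hri_analysis()] result
#'   and the output paths.
#' @export
run_hri_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  if (!cfg$input %in% c("simulate", "files"))
    stop("config error: input must be 'simulate' or 'files'")
  if (cfg$input == "files") {
    fd <- cfg$paths$fixture_dir
    if (is.null(fd) || !dir.exists(fd))
      stop("config error: paths$fixture_dir missing or does not exist")
    for (f in c("genes.gff3", "recmap.tsv", "covariates.tsv"))
      if (!file.exists(file.path(fd, f)))
        stop("config error: required input ", f, " not found in ", fd)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  drops <- list()
  log_fn <- function(iv, why) drops[[length(drops) + 1L]] <<-
    sprintf("exon [%d,%d) dropped: %s", iv[1], iv[2], why)
  gs <- if (cfg$input == "simulate") {
    params <- do.call(sim_params, cfg$sim)
    simulate_genes(params, seed = cfg$seed)
  } else {
    read_fixture_counts(cfg$paths$fixture_dir, cfg$n_chromosomes,
                        seed = cfg$seed,
                        core_margin_codons = cfg$core_margin_codons,
                        log_fn = log_fn)
  }
  n_chr <- if (!is.null(gs$truth)) gs$truth$params$n_chromosomes
           else cfg$n_chromosomes
  sp <- split_k4(gs$tab$D4, gs$tab$L4, parts = cfg$split_parts,
                 seed = cfg$seed + 1L)
  gs$tab <- cbind(gs$tab, sp)
  ana <- NULL
  if ("analysis" %in% cfg$stages)
    ana <- hri_analysis(gs, n_bins = cfg$n_bins, n_chromosomes = n_chr,
                        G = cfg$grid_size, rr_threshold = cfg$rr_threshold,
                        span = cfg$span, estimate_part = cfg$use_split_part,
                        n_parts = cfg$split_parts)
  # outputs
  genes_tsv <- file.path(cfg$out_dir, "genes.tsv")
  tabout <- gs$tab
  tabout$sfs0 <- serialize_sfs(gs$sfs0)
  tabout$sfs4 <- serialize_sfs(gs$sfs4)
  write.table(tabout, genes_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bins_tsv <- member_tsv <- hri_json <- NULL
  if (!is.null(ana)) {
    bins_tsv <- file.path(cfg$out_dir, "bins.tsv")
    write.table(ana$bins, bins_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    member_tsv <- file.path(cfg$out_dir, "bin_membership.tsv")
    memb <- do.call(rbind, lapply(seq_along(attr(ana$bins, "bins")),
                                  function(i)
      data.frame(gene_id = gs$tab$gene_id[attr(ana$bins, "bins")[[i]]],
                 bin = i)))
    write.table(memb, member_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    hri_json <- file.path(cfg$out_dir, "hri.json")
    hr <- if (cfg$clamp) ana$hri_clamped else ana$hri
    jsonlite::write_json(list(
      rr_threshold = cfg$rr_threshold, clamp = cfg$clamp,
      ka_no_hri = hr$ka_no_hri, total_no_hri = hr$total_no_hri,
      total_lost = hr$total_lost, f_hri = hr$f_hri,
      f_hri_unclamped = ana$hri$f_hri, f_hri_clamped = ana$hri_clamped$f_hri,
      per_bin_predictions = hr$per_bin_predictions,
      curvilinear = ana$curvilinear[c("a", "b", "c", "r2", "aic")],
      linear = ana$linear[c("a", "b", "r2", "aic")],
      model_p = ana$model_comparison$p), hri_json,
      auto_unbox = TRUE, digits = NA)
  }
  boot_tsv <- NULL
  if (cfg$bootstrap_B > 0 && !is.null(ana)) {
    ff <- pooled_fixation_factor(gs, n_chr, cfg$grid_size)$fixation_factor
    pipe <- function(g) {
      a <- hri_analysis(g, n_bins = cfg$n_bins, n_chromosomes = n_chr,
                        G = cfg$grid_size, rr_threshold = cfg$rr_threshold,
                        span = cfg$span, estimate_part = cfg$use_split_part,
                        n_parts = cfg$split_parts, fixation_factor = ff)
      c(f_hri = if (cfg$clamp) a$hri_clamped$f_hri else a$hri$f_hri)
    }
    bt <- bootstrap_pipeline(gs, pipe, B = cfg$bootstrap_B,
                             seed = cfg$seed + 2L)
    boot_tsv <- file.path(cfg$out_dir, "bootstrap.tsv")
    write.table(data.frame(replicate = seq_len(bt$B),
                           f_hri = bt$replicates[, 1]),
                boot_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("hriquant")),
    seed = cfg$seed, config = cfg[setdiff(names(cfg), "sim")],
    n_genes = nrow(gs$tab), n_chromosomes = n_chr,
    discarded_genes = if (is.null(ana)) 0L
                      else length(attr(ana$bins, "discarded")),
    drop_log = if (length(drops)) unlist(drops) else character(0)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(gene_set = gs, analysis = ana,
                 files = list(genes = genes_tsv, bins = bins_tsv,
                              membership = member_tsv, hri = hri_json,
                              bootstrap = boot_tsv, manifest = manifest)))
}

#' Validate a pipeline output directory
#'
#' Audits the conservation invariants across the written tables: the
#' hypergeometric split parts sum to the total 4-fold divergence for every
#' gene, pooled bin counts equal per-gene sums over the recorded
#' memberships, and the loss report satisfies the ratio identity
#' `f_hri = total_lost / total_no_hri` exactly.
#'
#' @param out_dir Directory written by [run_hri_pipeline()].
#' @param strict Stop on the first violation (default) instead of
#'   returning the problem list.
#' @return Invisibly, a list with `ok` and `problems`.
#' @export
validate_run <- function(out_dir, strict = TRUE) {
  problems <- character(0)
  need <- c("genes.tsv", "manifest.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    problems <- paste("missing output:", missing)
  } else {
    genes <- read.table(file.path(out_dir, "genes.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    if (all(c("d4_1", "d4_2", "d4_3") %in% names(genes))) {
      bad <- which(genes$d4_1 + genes$d4_2 + genes$d4_3 != genes$D4)
      if (length(bad))
        problems <- c(problems, paste("split closure violated for gene row",
                                      bad[1], "(", genes$gene_id[bad[1]], ")"))
    }
    if (file.exists(file.path(out_dir, "bins.tsv"))) {
      bins <- read.table(file.path(out_dir, "bins.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
      memb <- read.table(file.path(out_dir, "bin_membership.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
      pooled <- aggregate(cbind(L0, D0) ~ bin,
                          data = merge(memb, genes, by = "gene_id"),
                          FUN = sum)
      chk <- merge(bins[, c("bin", "L0", "D0")], pooled, by = "bin",
                   suffixes = c("_bin", "_genes"))
      bad <- which(chk$L0_bin != chk$L0_genes | chk$D0_bin != chk$D0_genes)
      if (length(bad))
        problems <- c(problems,
                      paste("pooled counts mismatch in bin", chk$bin[bad[1]]))
    }
    if (file.exists(file.path(out_dir, "hri.json"))) {
      hri <- jsonlite::read_json(file.path(out_dir, "hri.json"),
                                 simplifyVector = TRUE)
      if (abs(hri$f_hri - hri$total_lost / hri$total_no_hri) > 1e-12)
        problems <- c(problems,
                      "f_hri does not equal total_lost/total_no_hri")
    }
  }
  ok <- length(problems) == 0L
  if (!ok && strict)
    stop("validation failed:\n  ", paste(problems, collapse = "\n  "))
  invisible(list(ok = ok, problems = problems))
}
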