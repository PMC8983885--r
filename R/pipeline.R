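# End-to-end orchestration: simulate (or load) inputs, then run the
# analysis stages in dependency order (structure -> introns -> projection
# -> tree; synteny and coverage are independent). All outputs are new
# files in the run directory; a JSON manifest records the configuration
# hash, seed, versions and per-stage row counts, so identical
# config+inputs give identical manifests.

validation_error <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("paralogr_validation_error", "error", "condition")))
}

#' Pipeline configuration
#'
#' @param seed Integer seed; mandatory when any stochastic stage
#'   (simulation, bootstrap) is enabled.
#' @param stages Character vector of stages to run, from
#'   `simulate, introns, project, tree, synteny, coverage`.
#' @param inputs Named list of input paths used when `simulate` is not
#'   among the stages: `alignment` (aligned FASTA), `introns`
#'   (TSV), `gff3` + `genome` (FASTA) for gene models, `synteny_gff3` +
#'   `focal_genes`, `hits` + `domains` + `query_lengths` for coverage.
#' @param sim A [simulation_config()] (defaults to
#'   `simulation_config(seed)`) used by the simulate stage.
#' @param gamma_shape,n_rate_categories,n_bootstrap Tree-stage parameters
#'   (see [phylo_config()]).
#' @param k,window Synteny parameters (see [extract_neighborhood()]).
#' @param cov_min,evalue_max Coverage parameters (see
#'   [classify_homology()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = NULL,
                            stages = c("simulate", "introns", "project",
                                       "tree", "synteny"),
                            inputs = list(), sim = NULL,
                            gamma_shape = NULL, n_rate_categories = 5L,
                            n_bootstrap = 1000L, k = 4L, window = 500000L,
                            cov_min = 0.60, evalue_max = 1e-20) {
  known <- c("simulate", "introns", "project", "tree", "synteny", "coverage")
  bad <- setdiff(stages, known)
  if (length(bad)) validation_error(paste0("unknown stage: ", bad[1]))
  stochastic <- any(c("simulate", "tree") %in% stages)
  if (stochastic && is.null(seed))
    validation_error("seed is mandatory when a stochastic stage is enabled")
  for (p in unlist(inputs))
    if (!file.exists(p)) validation_error(paste0("input does not exist: ", p))
  if ("simulate" %in% stages && is.null(sim))
    sim <- simulation_config(seed)
  structure(list(seed = seed, stages = stages, inputs = inputs, sim = sim,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 n_bootstrap = as.integer(n_bootstrap),
                 k = as.integer(k), window = as.integer(window),
                 cov_min = cov_min, evalue_max = evalue_max),
            class = "pipeline_config")
}

.manifest_entry <- function(files, rows) {
  list(outputs = as.list(basename(files)), rows = rows)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes all outputs
#' plus `manifest.json` into `out_dir`. Identical configuration and
#' inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; must be empty or absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    validation_error(paste0("run directory not empty: ", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "paralogr",
                   version = as.character(utils::packageVersion("paralogr")),
                   seed = config$seed, stages = list())
  st <- config$stages
  truth <- NULL; models <- NULL; introns <- NULL; aln <- NULL

  if ("simulate" %in% st) {
    truth <- simulate_family(config$sim)
    sim_dir <- file.path(out_dir, "sim")
    write_family(truth, sim_dir)
    models <- lapply(truth$members, `[[`, "model")
    aln <- truth$alignment
    manifest$stages$simulate <-
      .manifest_entry(dir(sim_dir, full.names = TRUE),
                      length(truth$members))
  } else {
    if (!is.null(config$inputs$alignment))
      aln <- alignment(read_fasta(config$inputs$alignment, "protein"))
    if (!is.null(config$inputs$gff3) && !is.null(config$inputs$genome)) {
      ann <- read_gff3(config$inputs$gff3)
      genome <- read_fasta(config$inputs$genome, "dna")
      models <- gene_models_from_gff3(ann, genome)
    }
  }

  if ("introns" %in% st) {
    if (is.null(models) && !is.null(config$inputs$introns)) {
      introns <- read_introns_tsv(config$inputs$introns)
    } else {
      if (is.null(models))
        validation_error("introns stage needs gene models or an introns TSV")
      introns <- do.call(rbind, lapply(models, extract_introns))
    }
    f <- file.path(out_dir, "introns.tsv")
    write_introns_tsv(introns, f)
    manifest$stages$introns <- .manifest_entry(f, nrow(introns))
  }

  if ("project" %in% st) {
    if (is.null(aln)) validation_error("project stage needs an alignment")
    if (is.null(introns)) validation_error("project stage needs introns")
    map <- project_introns(aln, introns)
    cons <- intron_conservation(map)
    f <- file.path(out_dir, "intron_conservation.tsv")
    write_conservation_tsv(cons, f)
    manifest$stages$project <- .manifest_entry(f, nrow(cons$columns))
  }

  if ("tree" %in% st) {
    if (is.null(aln)) validation_error("tree stage needs an alignment")
    pcfg <- phylo_config(gamma_shape = config$gamma_shape,
                         n_rate_categories = config$n_rate_categories,
                         n_bootstrap = config$n_bootstrap,
                         seed = config$seed)
    d <- jtt_distance_matrix(aln, config$gamma_shape,
                             config$n_rate_categories)
    fd <- file.path(out_dir, "distances.tsv")
    write_distance_tsv(d, fd)
    tree <- bootstrap_support(aln, pcfg)
    rooted <- midpoint_root(tree)
    ft <- file.path(out_dir, "tree.nwk")
    write_newick(rooted, ft)
    manifest$stages$tree <- .manifest_entry(c(fd, ft), nrow(d))
  }

  if ("synteny" %in% st) {
    nbhds <- NULL
    if (!is.null(truth)) {
      nbhds <- lapply(truth$members, `[[`, "neighborhood")
    } else if (!is.null(config$inputs$synteny_gff3) &&
               !is.null(config$inputs$focal_genes)) {
      ann <- read_gff3(config$inputs$synteny_gff3)
      focal <- readLines(config$inputs$focal_genes)
      focal <- focal[nzchar(focal) & !grepl("^#", focal)]
      nbhds <- lapply(focal, function(g)
        extract_neighborhood(ann, g, k = config$k, window = config$window))
      names(nbhds) <- focal
    }
    if (is.null(nbhds))
      validation_error("synteny stage needs simulated members or gff3+focal list")
    fn <- file.path(out_dir, "neighborhoods.tsv")
    write_neighborhoods_tsv(nbhds, fn)
    ids <- names(nbhds)
    blocks <- list()
    if (length(ids) > 1L) {
      for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids)))
        blocks[[length(blocks) + 1L]] <-
          conserved_blocks(nbhds[[i]], nbhds[[j]])
    }
    fb <- file.path(out_dir, "synteny_blocks.tsv")
    write_blocks_tsv(blocks, fb)
    manifest$stages$synteny <- .manifest_entry(c(fn, fb), length(blocks))
  }

  if ("coverage" %in% st) {
    ins <- config$inputs
    if (is.null(ins$hits) || is.null(ins$domains) || is.null(ins$query_lengths))
      validation_error("coverage stage needs hits, domains and query_lengths inputs")
    hits <- read_hit_table(ins$hits)
    domains <- read.table(ins$domains, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("query_id", "name", "start", "end"),
                          stringsAsFactors = FALSE)
    ql <- read.table(ins$query_lengths, sep = "\t", header = FALSE,
                     comment.char = "#",
                     col.names = c("query_id", "length"),
                     stringsAsFactors = FALSE)
    classes <- classify_hit_table(hits, domains,
                                  setNames(ql$length, ql$query_id),
                                  cov_min = config$cov_min,
                                  evalue_max = config$evalue_max)
    f <- file.path(out_dir, "homology_classes.tsv")
    write_classification_tsv(classes, f)
    manifest$stages$coverage <- .manifest_entry(f, nrow(classes))
  }

  # configuration hash + output checksums (order-stable)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "sim")],
                               auto_unbox = TRUE, null = "null", digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  outs <- sort(setdiff(dir(out_dir, recursive = TRUE),
                       c("manifest.json")))
  sums <- tools::md5sum(file.path(out_dir, outs))
  manifest$outputs <- as.list(setNames(unname(sums), outs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
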