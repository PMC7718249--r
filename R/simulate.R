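#' Configuration for the three-group 3' RNA-seq count simulator
#'
#' The defaults reproduce the study design emulated by the package: three
#' diagnostic groups of 7 conjunctival squamous cell carcinomas (SCC), 7
#' papillomas (Pap) and 10 healthy conjunctiva (Ctrl), negative-binomial
#' counts with gene-wise dispersion, log-normal library-size factors, 50
#' planted group-specific up-regulated markers per group with log2 fold
#' changes in [2.5, 6], a 30-gene shared tumor signature (up in SCC and Pap
#' versus Ctrl) and the remainder null genes. An optional batch shift is
#' added on the log2 scale.
#'
#' @param n_genes total number of genes.
#' @param group_sizes named integer vector of samples per group; all sizes
#'   must be >= 2 so leave-one-out centroids remain computable.
#' @param n_markers_per_group planted up-regulated markers per group.
#' @param n_shared_tumor_genes genes up-regulated in both tumor groups
#'   (SCC and Pap) relative to Ctrl.
#' @param marker_log2fc_range range (> 0) the planted log2 fold changes are
#'   drawn from, uniformly.
#' @param baseline_log2_mean_range range of baseline means on the log2
#'   normalized-count scale, drawn uniformly so that low- and high-expression
#'   genes both occur.
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); scalar or per-gene vector.
#' @param libsize_log_sd standard deviation of the natural-log library-size
#'   factors (log-normal, median 1).
#' @param batch optional per-sample batch labels (length = total samples);
#'   the first label in appearance order is the reference batch.
#' @param batch_shift_log2 additive shift on the log2 mean applied to all
#'   non-reference batches.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `sim_config` list, validated against its invariants.
#' @seealso [simulate_counts()], [simulate_null_counts()]
#' @export
sim_config <- function(n_genes = 2000L,
                       group_sizes = c(SCC = 7L, Pap = 7L, Ctrl = 10L),
                       n_markers_per_group = 50L,
                       n_shared_tumor_genes = 30L,
                       marker_log2fc_range = c(2.5, 6),
                       baseline_log2_mean_range = c(1, 10),
                       dispersion = 0.2,
                       libsize_log_sd = 0.25,
                       batch = NULL,
                       batch_shift_log2 = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              n_markers_per_group = as.integer(n_markers_per_group),
              n_shared_tumor_genes = as.integer(n_shared_tumor_genes),
              marker_log2fc_range = marker_log2fc_range,
              baseline_log2_mean_range = baseline_log2_mean_range,
              dispersion = dispersion, libsize_log_sd = libsize_log_sd,
              batch = batch, batch_shift_log2 = batch_shift_log2,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L)
    .stopf("invalid simulation config: n_genes must be positive")
  if (is.null(names(cfg$group_sizes)) || anyDuplicated(names(cfg$group_sizes)))
    .stopf("invalid simulation config: group_sizes must have unique group names")
  if (any(cfg$group_sizes < 2L))
    .stopf("invalid simulation config: all group sizes must be >= 2 (leave-one-out centroids)")
  planted <- cfg$n_markers_per_group * length(cfg$group_sizes) + cfg$n_shared_tumor_genes
  if (cfg$n_markers_per_group < 0L || cfg$n_shared_tumor_genes < 0L)
    .stopf("invalid simulation config: planted gene counts must be non-negative")
  if (planted > cfg$n_genes)
    .stopf("invalid simulation config: planted genes (%d) exceed n_genes (%d)",
           planted, cfg$n_genes)
  if (cfg$n_markers_per_group > 0L && cfg$marker_log2fc_range[1L] <= 0)
    .stopf("invalid simulation config: marker_log2fc_range lower bound must be > 0")
  if (any(cfg$dispersion <= 0))
    .stopf("invalid simulation config: dispersion must be positive")
  if (cfg$libsize_log_sd < 0)
    .stopf("invalid simulation config: libsize_log_sd must be non-negative")
  n <- sum(cfg$group_sizes)
  if (!is.null(cfg$batch) && length(cfg$batch) != n)
    .stopf("invalid simulation config: batch must have one label per sample (%d)", n)
  invisible(cfg)
}

## Run expr with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate three-group negative-binomial counts with planted markers
#'
#' Counts are drawn independently per gene and sample from a negative
#' binomial with mean `baseline * 2^log2fc(role, group) * libfactor` (times
#' `2^batch_shift_log2` for non-reference batches) and variance
#' `mu + dispersion * mu^2`. Feature lengths are drawn uniformly in
#' [200, 5000] bp so TPM computation can be exercised; lengths play no role
#' in the counts themselves (3' tag counting has no length bias).
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   * `counts`: a [count_matrix()],
#'   * `sheet`: sample sheet data.frame (`sample_id`, `group`, `batch`,
#'     `sex`, `year`),
#'   * `truth`: ground truth — `genes` data.frame (`gene_id`, `role` in
#'     marker/shared_tumor/null, `group`, `true_log2fc`), `groups` (named by
#'     sample), `lib_factors` (named by sample).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$genes$role)
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    sample_ids <- unlist(lapply(names(config$group_sizes), function(g)
      paste0(g, "_", seq_len(config$group_sizes[[g]]))))
    gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))

    ## gene roles: per-group marker blocks, then shared tumor block, then null
    role <- rep("null", config$n_genes)
    role_group <- rep(NA_character_, config$n_genes)
    true_lfc <- rep(0, config$n_genes)
    pos <- 0L
    for (g in names(config$group_sizes)) {
      if (config$n_markers_per_group > 0L) {
        idx <- pos + seq_len(config$n_markers_per_group)
        role[idx] <- "marker"
        role_group[idx] <- g
        true_lfc[idx] <- stats::runif(length(idx), config$marker_log2fc_range[1L],
                                      config$marker_log2fc_range[2L])
        pos <- pos + config$n_markers_per_group
      }
    }
    if (config$n_shared_tumor_genes > 0L) {
      idx <- pos + seq_len(config$n_shared_tumor_genes)
      role[idx] <- "shared_tumor"
      true_lfc[idx] <- stats::runif(length(idx), config$marker_log2fc_range[1L],
                                    config$marker_log2fc_range[2L])
    }

    baseline <- 2^stats::runif(config$n_genes, config$baseline_log2_mean_range[1L],
                               config$baseline_log2_mean_range[2L])
    libf <- stats::rlnorm(n, meanlog = 0, sdlog = config$libsize_log_sd)
    names(libf) <- sample_ids

    ## log2 fold-change contribution per gene x sample
    tumor_groups <- names(config$group_sizes)[seq_len(min(2L, length(config$group_sizes)))]
    lfc_mat <- matrix(0, config$n_genes, n)
    for (j in seq_len(n)) {
      up <- (role == "marker" & role_group == groups[j]) |
        (role == "shared_tumor" & groups[j] %in% tumor_groups)
      lfc_mat[up, j] <- true_lfc[up]
    }

    mu <- baseline * 2^lfc_mat
    mu <- sweep(mu, 2L, libf, `*`)
    if (!is.null(config$batch) && config$batch_shift_log2 != 0) {
      shifted <- config$batch != config$batch[1L]
      mu[, shifted] <- mu[, shifted] * 2^config$batch_shift_log2
    }

    size <- 1 / config$dispersion  # NB size parameter; recycled over genes
    counts <- matrix(stats::rnbinom(config$n_genes * n, mu = mu, size = size),
                     config$n_genes, n, dimnames = list(gene_ids, sample_ids))
    lengths <- sample(200:5000, config$n_genes, replace = TRUE)

    sheet <- data.frame(sample_id = sample_ids, group = groups,
                        batch = if (is.null(config$batch)) NA_character_
                                else as.character(config$batch),
                        sex = NA_character_, year = NA_integer_,
                        stringsAsFactors = FALSE)
    truth <- list(
      genes = data.frame(gene_id = gene_ids, role = role, group = role_group,
                         true_log2fc = true_lfc, stringsAsFactors = FALSE),
      groups = stats::setNames(groups, sample_ids),
      lib_factors = libf)
    list(counts = count_matrix(counts, lengths), sheet = sheet, truth = truth)
  })
}

#' Simulate signal-free counts for type-I-error testing
#'
#' Same generative model as [simulate_counts()] with no planted markers and
#' no shared tumor signature: every gene is null and the group labels carry
#' no information.
#'
#' @inheritParams simulate_counts
#' @return as [simulate_counts()]; all gene roles are `"null"`.
#' @export
simulate_null_counts <- function(config) {
  config$n_markers_per_group <- 0L
  config$n_shared_tumor_genes <- 0L
  simulate_counts(config)
}

#' Write a counts fixture and sample sheet to disk
#'
#' Emits a featureCounts-dialect TSV (`Geneid`, `Chr`, `Start`, `End`,
#' `Strand`, `Length`, one column per sample, preceded by a `#` program
#' line) and a sample-sheet CSV with header
#' `sample_id,group,batch,sex,year`. Both round-trip through
#' [read_counts_table()] and [read_sample_sheet()].
#'
#' @param counts a [count_matrix()].
#' @param sheet sample sheet data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of the two files written
#'   (`counts.tsv`, `samples.csv`).
#' @export
write_fixture <- function(counts, sheet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- .counts_of(counts)
  lens <- .lengths_of(counts) %||% rep(1000, nrow(m))
  ann <- if (inherits(counts, "count_matrix")) counts$annotation else NULL
  tab <- data.frame(Geneid = as.character(rownames(m) %||% character(0)),
                    Chr = ann$Chr %||% rep("chr1", nrow(m)),
                    Start = ann$Start %||% rep(1L, nrow(m)),
                    End = ann$End %||% as.integer(lens),
                    Strand = ann$Strand %||% rep("+", nrow(m)),
                    Length = as.integer(lens),
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(m, check.names = FALSE))
  counts_path <- file.path(dir, "counts.tsv")
  sheet_path <- file.path(dir, "samples.csv")
  con <- file(counts_path, "w")
  on.exit(close(con))
  writeLines("# Program:maceclass simulator", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- as.data.frame(sheet)
  for (col in c("batch", "sex", "year")) if (is.null(sheet[[col]])) sheet[[col]] <- NA
  utils::write.csv(sheet[, c("sample_id", "group", "batch", "sex", "year")],
                   sheet_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(counts = counts_path, sheet = sheet_path))
}
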