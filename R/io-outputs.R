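#' Read a passport table
#'
#' CSV with one row per accession: `sample_id`, `latitude`, `longitude`,
#' `altitude`, `ecotype`, `group`, `sowing_doy`, `harvest_doy` (missing
#' optional columns are tolerated; coordinates are validated).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_passports <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("sample_id", "latitude", "longitude") %in% names(x))) {
    stop("passport table needs sample_id, latitude, longitude",
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids",
                                       call. = FALSE)
  with(x, stopifnot(all(latitude >= -90 & latitude <= 90, na.rm = TRUE),
                    all(longitude >= -180 & longitude <= 360,
                        na.rm = TRUE)))
  x
}

#' Read a trait table
#'
#' CSV with `sample_id` plus named numeric trait columns (flowering time
#' per location, TAR, AP, ...).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_traits <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(x)) {
    stop("trait table needs a sample_id column", call. = FALSE)
  }
  x
}

#' Read a candidate-gene/QTL interval table
#'
#' Tab-delimited with columns `chrom`, `start`, `end`, `name`
#' (1-based closed intervals).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_intervals <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path,
                                           stringsAsFactors = FALSE))
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) file of pipeline settings; unknown keys are rejected
#' and referenced input paths must exist.
#'
#' @param path configuration file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("vcf", "passports", "traits", "intervals", "out_dir",
             "seed", "log_level", "sim", "maf_min", "het_max",
             "missing_max", "sample_missing_max", "min_hom_minor",
             "impute_method", "n_pcs", "alpha", "core_panel",
             "bin_sizes", "max_qtn", "fst_quantile", "min_delta",
             "maf_threshold", "window_fst_bp", "window_theta_bp")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("vcf", "passports", "traits", "intervals")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("input path does not exist: ", cfg[[key]], call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Write pipeline outputs
#'
#' Association results as tab-delimited text (chromosome, position, MAF,
#' effect, p, PVE), trees as Newick, LD blocks as BED (0-based
#' half-open, converted from the internal 1-based closed convention),
#' other reports as CSV, plus a JSON manifest carrying the configuration
#' hash, seed and package version. The output directory must be
#' writable before anything is written.
#'
#' @param results named list; recognized elements: `assoc`
#'   (`assoc_result`, may carry a `pve` column), `tree` (`phylo`),
#'   `blocks` (tibble from [ld_block()]), and any other data frames
#'   (written as `<name>.csv`).
#' @param dir output directory (created if needed).
#' @param config list used to compute the manifest hash.
#' @param seed integer recorded in the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(results, dir, config = list(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    stop("output directory not writable: ", dir, call. = FALSE)
  }
  written <- character(0)
  out <- function(f) { written <<- c(written, f); f }
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "assoc_result")) {
      tab <- data.frame(chromosome = obj$chrom, position = obj$pos,
                        maf = obj$maf, effect = obj$beta, p = obj$p,
                        pve = if ("pve" %in% names(obj)) obj$pve
                              else NA_real_)
      utils::write.table(tab, out(file.path(dir, paste0(nm, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (inherits(obj, "phylo")) {
      ape::write.tree(obj, out(file.path(dir, paste0(nm, ".nwk"))))
    } else if (is.data.frame(obj) &&
               all(c("chrom", "start", "end") %in% names(obj))) {
      bed <- data.frame(chrom = obj$chrom, start = obj$start - 1L,
                        end = obj$end,
                        name = if ("focal_pos" %in% names(obj)) {
                          paste0(obj$chrom, ":", obj$focal_pos)
                        } else ".")
      utils::write.table(bed, out(file.path(dir, paste0(nm, ".bed"))),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    } else if (is.data.frame(obj)) {
      utils::write.csv(obj, out(file.path(dir, paste0(nm, ".csv"))),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    config_hash = rlang::hash(config), seed = seed,
    package_version = as.character(utils::packageVersion("ecogwas")),
    files = basename(written), timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out(file.path(dir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(written)
}

#' Run the full pipeline on a simulated panel
#'
#' End-to-end orchestration used for demonstrations and smoke tests:
#' simulate a structured panel, call genotypes from read depths, apply
#' the filtering cascade and imputation, characterize structure, LD and
#' diversity, scan flowering time and the bioclimatic variables,
#' quantify effects and heritability, classify selection signals, and
#' write all outputs with a manifest. Per-stage record counts (sites and
#' samples in and out of every filter) are reported via messages.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param alpha family-wise error rate for the significance threshold
#'   (default 0.01; the threshold is `alpha` / number of SNPs).
#' @param n_pcs number of principal-component covariates in the scans.
#' @return A named list of all stage results (invisibly writes files).
#' @export
run_pipeline <- function(config, out_dir, alpha = 0.01, n_pcs = 3L) {
  panel <- simulate_panel(config)
  message("simulated ", ncol(panel$genotypes$geno), " samples x ",
          nrow(panel$genotypes$geno), " SNPs")

  mask <- discover_sites(panel$depths)
  message("site discovery: ", sum(mask), "/", length(mask), " retained")
  called <- call_genotypes(panel$depths[mask, ])
  filt <- filter_sites_pre(called)
  message("pre-imputation site filter: ", nrow(filt$geno), " sites")
  filt <- filter_samples(filt)
  message("sample filter: ", ncol(filt$geno), " samples (",
          attr(filt, "n_removed"), " removed)")
  imp <- impute_genotypes(filt, method = "mode")
  final <- filter_sites_post(imp, min_homozygous_minor =
                               max(2L, round(ncol(imp$geno) * 0.01)))
  message("post-imputation filter: ", nrow(final$geno), " sites")

  keep <- match(final$samples, panel$samples$sample_id)
  samples <- panel$samples[keep, ]
  phen <- panel$phenotypes[keep, ]

  k <- relationship_matrix(final)
  pcs <- pca(k, k = 10)
  groups <- assign_groups(pcs, latitude = samples$latitude,
                          is_wild = samples$group == "WILD",
                          seed = config$seed)
  tree <- nj_tree(allele_sharing_distance(
    final[, seq_len(min(80, ncol(final$geno)))]))

  pairs <- ld_r2(final)
  profile <- ld_decay_profile(pairs)
  theta <- watterson_theta(final)

  covar <- as.matrix(pcs$coords[, 1 + seq_len(n_pcs)])
  thr <- bonferroni_threshold(alpha, nrow(final$geno))
  traits <- dplyr::inner_join(samples, phen, by = "sample_id")
  scans <- lapply(
    stats::setNames(nm = c("FT_loc1", "FT_loc2", "MDL", "TAR", "AP")),
    function(tr) scan_farmcpu(final, traits[[tr]], covar,
                              trait_name = tr))
  tas <- dplyr::bind_rows(lapply(scans, function(s) {
    keep <- !is.na(s$p) & s$p < thr$threshold
    tibble::tibble(chrom = s$chrom[keep], pos = s$pos[keep],
                   p = s$p[keep], beta = s$beta[keep])
  }), .id = "trait")
  tas_sites <- dplyr::distinct(tas, .data$chrom, .data$pos)
  message("significant associations: ", nrow(tas), " (",
          nrow(tas_sites), " unique TASs) at p < ",
          format(thr$threshold, digits = 3))

  herit <- heritability(k, traits$FT_loc1, covar)
  results <- list(samples = samples, groups = groups,
                  ld_profile = profile$bins, theta = theta)
  results[paste0("scan_", names(scans))] <- scans
  if (nrow(tas_sites) > 0) {
    blocks <- dplyr::bind_rows(lapply(seq_len(nrow(tas_sites)),
      function(r) ld_block(final, tas_sites$chrom[r], tas_sites$pos[r])))
    pv <- pve(final[sort(unique(match_tas(final, tas_sites))), ],
              traits$FT_loc1)
    dom <- domestication_scan(final, samples$group == "WILD",
                              samples$group != "WILD", tas_sites)
    div <- diversification_scan(final, samples$group, tas_sites)
    sel <- classify_selection(dom, div)
    results <- c(results, list(
      tas = tas, blocks = blocks,
      pve = pv$per_tas,
      selection = dplyr::mutate(
        sel$per_tas,
        category = as.character(.data$category))))
  }
  results$heritability <- tibble::tibble(
    trait = "FT_loc1", sigma_a2 = herit$sigma_a2,
    sigma_e2 = herit$sigma_e2, h2 = herit$h2,
    converged = herit$converged)
  results$tree <- tree
  write_outputs(results, out_dir, config = unclass(config),
                seed = config$seed)
  invisible(results)
}
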