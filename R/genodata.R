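#' Construct a genotype dataset
#'
#' The central container of the package: a samples-by-SNPs matrix of minor
#' allele counts together with the variant records describing each SNP.
#' Genotypes code the number of copies of `allele_b` carried by each diploid
#' individual, so every non-missing entry is 0, 1 or 2; missing genotypes are
#' `NA`. By convention `allele_b` is the dataset-wide minor allele (ties broken
#' lexicographically), so that genotype codes count minor-allele copies.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample identifiers.
#' @param variants data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`. `chrom` is kept as text (so "X" is admissible),
#'   `pos` is a 1-based base-pair position.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `samples` and `variants`.
#' @export
genotype_dataset <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.character(samples)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(genotypes) != length(samples)) {
    stop("genotype matrix has ", nrow(genotypes), " rows but ", length(samples),
         " sample IDs")
  }
  if (ncol(genotypes) != nrow(variants)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(variants), " variant records")
  }
  if (anyDuplicated(samples)) stop("sample IDs are not unique")
  if (anyDuplicated(variants$snp_id)) stop("snp_ids are not unique")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing genotype codes must lie in {0, 1, 2}")
  }
  if (any(!is.na(variants$pos) & variants$pos < 1L)) {
    stop("variant positions must be >= 1")
  }
  same <- !is.na(variants$allele_a) & !is.na(variants$allele_b) &
    variants$allele_a == variants$allele_b
  if (any(same)) {
    stop("allele_a equals allele_b for: ",
         paste(utils::head(variants$snp_id[same], 5), collapse = ", "))
  }
  dimnames(genotypes) <- list(samples, variants$snp_id)
  structure(list(genotypes = genotypes, samples = samples, variants = variants),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$variants), "SNPs\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Number of samples / variants in a dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) length(ds$samples)

#' @rdname n_samples
#' @export
n_variants <- function(ds) nrow(ds$variants)

#' Subset a genotype dataset
#'
#' @param ds a `genotype_dataset`.
#' @param samples sample IDs (or logical/integer index) to keep; `NULL` keeps all.
#' @param snps snp_ids (or logical/integer index) to keep; `NULL` keeps all.
#' @return the subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  ridx <- if (is.null(samples)) seq_along(ds$samples) else resolve_index(samples, ds$samples, "sample")
  cidx <- if (is.null(snps)) seq_len(nrow(ds$variants)) else resolve_index(snps, ds$variants$snp_id, "snp")
  genotype_dataset(ds$genotypes[ridx, cidx, drop = FALSE],
                   ds$samples[ridx],
                   ds$variants[cidx, , drop = FALSE])
}

resolve_index <- function(idx, universe, what) {
  if (is.character(idx)) {
    pos <- match(idx, universe)
    if (anyNA(pos)) stop("unknown ", what, " ID(s): ",
                         paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else {
    as.integer(idx)
  }
}

## ---- PED/MAP I/O -----------------------------------------------------------

#' Read genotypes from PLINK text PED/MAP files
#'
#' The MAP file supplies one row per SNP (`chrom`, `snp_id`, genetic distance,
#' `pos`); the PED file one row per sample with six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two allele
#' characters per SNP. "0 0" denotes a missing genotype. `allele_b` is chosen
#' as the dataset-wide minor allele (lexicographic tie-break) and genotype
#' codes count copies of it.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_fields) > 0 && any(lengths(map_fields) < 4)) {
    stop("MAP line ", which(lengths(map_fields) < 4)[1], " has fewer than 4 fields")
  }
  n_snp <- length(map_fields)
  chrom <- vapply(map_fields, `[`, "", 1)
  snp_id <- vapply(map_fields, `[`, "", 2)
  pos <- as.integer(vapply(map_fields, `[`, "", 4))

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_sample <- length(ped_lines)
  expected <- 6L + 2L * n_snp
  samples <- character(n_sample)
  # allele characters per sample per SNP, two n_sample x n_snp matrices
  al1 <- matrix(NA_character_, n_sample, n_snp)
  al2 <- matrix(NA_character_, n_sample, n_snp)
  for (i in seq_len(n_sample)) {
    fields <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(fields) != expected) {
      stop("PED line ", i, " has ", length(fields), " fields; expected ", expected)
    }
    samples[i] <- fields[2]
    if (n_snp > 0) {
      g <- fields[-(1:6)]
      al1[i, ] <- g[seq(1, length(g), by = 2)]
      al2[i, ] <- g[seq(2, length(g), by = 2)]
    }
  }
  al1[al1 == "0"] <- NA_character_
  al2[al2 == "0"] <- NA_character_
  half_missing <- xor(is.na(al1), is.na(al2))
  if (any(half_missing)) {
    stop("half-missing genotype (one allele '0') at PED line ",
         which(rowSums(half_missing) > 0)[1])
  }

  geno <- matrix(NA_integer_, n_sample, n_snp)
  allele_a <- character(n_snp)
  allele_b <- character(n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(al1[, j], al2[, j])
    obs <- obs[!is.na(obs)]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) {
      stop("SNP ", snp_id[j], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    }
    if (length(alleles) == 0) {
      allele_a[j] <- "A"; allele_b[j] <- NA_character_
      next
    }
    if (length(alleles) == 1) {
      allele_a[j] <- alleles[1]
      allele_b[j] <- NA_character_
      geno[, j] <- ifelse(is.na(al1[, j]), NA_integer_, 0L)
      next
    }
    counts <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele is allele_b; lexicographic tie-break (alleles already sorted)
    minor <- if (counts[1] <= counts[2]) alleles[1] else alleles[2]
    major <- setdiff(alleles, minor)
    allele_a[j] <- major
    allele_b[j] <- minor
    geno[, j] <- (al1[, j] == minor) + (al2[, j] == minor)
  }
  variants <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  genotype_dataset(geno, samples, variants)
}

#' Write a genotype dataset to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: re-reading the written files yields a dataset
#' with identical sample IDs, variant order and genotype codes.
#'
#' @param ds a `genotype_dataset`.
#' @param ped_path,map_path output paths.
#' @return invisibly, `NULL`.
#' @export
write_ped_map <- function(ds, ped_path, map_path) {
  v <- ds$variants
  map <- paste(v$chrom, v$snp_id, 0, v$pos, sep = "\t")
  writeLines(map, map_path)
  n <- n_samples(ds)
  L <- n_variants(ds)
  a <- ifelse(is.na(v$allele_a), "A", v$allele_a)
  b <- ifelse(is.na(v$allele_b), "B", v$allele_b)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- ds$genotypes[i, ]
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 1, b, a))
    c2 <- ifelse(is.na(g), "0", ifelse(g == 2, b, a))
    lines[i] <- paste(c(ds$samples[i], ds$samples[i], 0, 0, 0, -9,
                        as.vector(rbind(c1, c2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(NULL)
}

## ---- sample metadata -------------------------------------------------------

#' Allowed region labels
#' @export
REGIONS <- c("North", "Centre", "South")

#' Read a sample metadata table
#'
#' A delimited text file (TSV or CSV, sniffed from the header line) with
#' columns `sample_id`, `state`, `region`, `latitude` and optionally
#' `longitude`. Regions must be one of North/Centre/South and latitudes valid
#' decimal degrees.
#'
#' @param path path to the metadata file.
#' @return data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  required <- c("sample_id", "state", "region", "latitude")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_region <- !md$region %in% REGIONS
  if (any(bad_region)) {
    stop("unknown region label(s): ",
         paste(unique(md$region[bad_region]), collapse = ", "))
  }
  lat <- suppressWarnings(as.numeric(md$latitude))
  if (anyNA(lat)) stop("unparseable latitude at row ", which(is.na(lat))[1])
  if (any(abs(lat) > 90)) {
    stop("latitude out of [-90, 90] at row ", which(abs(lat) > 90)[1])
  }
  md$latitude <- lat
  if ("longitude" %in% names(md)) {
    lon <- suppressWarnings(as.numeric(md$longitude))
    if (any(!is.na(md$longitude) & is.na(lon))) stop("unparseable longitude")
    md$longitude <- lon
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' Packaged state-region-latitude lookup
#'
#' The packaged categorization of the 11 Peninsular Malaysian states (plus
#' Singapore) into North/Centre/South regions with their latitude coordinates
#' and post-QC subject counts. One printed subject count spans three northern
#' states in the source table; it is recorded on the first of them and `NA`
#' on the other two.
#'
#' @return data frame with columns `state`, `region`, `latitude`, `n_subjects`.
#' @export
state_region_table <- function() {
  path <- system.file("extdata", "state_regions.tsv", package = "finestruct",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Map state names to regions via the packaged lookup
#' @param states character vector of state names.
#' @return character vector of region labels.
#' @export
region_of_state <- function(states) {
  tab <- state_region_table()
  idx <- match(states, tab$state)
  if (anyNA(idx)) {
    stop("unknown state(s): ", paste(unique(states[is.na(idx)]), collapse = ", "))
  }
  tab$region[idx]
}

#' Packaged table of highly differentiated SNPs
#'
#' The packaged list of the most differentiated SNPs between the northern and
#' southern regional samples (per-SNP F_ST > 0.05 as printed, with each
#' region's own minor allele frequency).
#'
#' @return data frame with columns `snp_id`, `chrom`, `pos`, `minor_allele`,
#'   `fst`, `maf_north`, `maf_south`, `gene`, `category`.
#' @export
top_fst_table <- function() {
  path <- system.file("extdata", "top_fst_snps.tsv", package = "finestruct",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"), fill = TRUE)
}

## ---- merging and counting --------------------------------------------------

#' Merge genotype datasets on shared SNPs
#'
#' Variants are intersected by `snp_id`; allele codes are harmonized to the
#' first dataset's orientation (a dataset whose `allele_a`/`allele_b` are
#' exchanged at a SNP has its codes flipped `g -> 2 - g` there). Samples are
#' concatenated in input order and must be disjoint across datasets.
#'
#' @param ds_list list of two or more `genotype_dataset` objects.
#' @return the merged `genotype_dataset`.
#' @export
merge_datasets <- function(ds_list) {
  if (length(ds_list) < 2) stop("need at least two datasets to merge")
  all_samples <- unlist(lapply(ds_list, function(d) d$samples))
  if (anyDuplicated(all_samples)) {
    stop("sample IDs overlap across datasets: ",
         paste(utils::head(unique(all_samples[duplicated(all_samples)]), 5),
               collapse = ", "))
  }
  shared <- Reduce(intersect, lapply(ds_list, function(d) d$variants$snp_id))
  ref <- ds_list[[1]]
  ref_idx <- match(shared, ref$variants$snp_id)
  ref_var <- ref$variants[ref_idx, , drop = FALSE]
  blocks <- vector("list", length(ds_list))
  blocks[[1]] <- ref$genotypes[, ref_idx, drop = FALSE]
  for (k in seq_along(ds_list)[-1]) {
    d <- ds_list[[k]]
    idx <- match(shared, d$variants$snp_id)
    v <- d$variants[idx, , drop = FALSE]
    g <- d$genotypes[, idx, drop = FALSE]
    same <- !is.na(v$allele_a) & !is.na(v$allele_b) &
      v$allele_a == ref_var$allele_a & v$allele_b == ref_var$allele_b
    swapped <- !is.na(v$allele_a) & !is.na(v$allele_b) &
      v$allele_a == ref_var$allele_b & v$allele_b == ref_var$allele_a
    # monomorphic sites (allele_b NA) are compatible if the observed allele
    # matches either of the reference alleles
    mono <- is.na(v$allele_b)
    mono_ok <- mono & (v$allele_a == ref_var$allele_a |
                         (!is.na(ref_var$allele_b) & v$allele_a == ref_var$allele_b))
    mono_flip <- mono_ok & !is.na(ref_var$allele_b) & v$allele_a == ref_var$allele_b
    bad <- !(same | swapped | mono_ok)
    if (any(bad)) {
      stop("incompatible allele pairs at SNP(s): ",
           paste(utils::head(shared[bad], 5), collapse = ", "))
    }
    flip <- swapped | mono_flip
    if (any(flip)) {
      g[, flip] <- 2L - g[, flip, drop = FALSE]
    }
    blocks[[k]] <- g
  }
  genotype_dataset(do.call(rbind, blocks), all_samples, ref_var)
}

#' Allele counts at one SNP over a sample subset
#'
#' Counts are taken over non-missing genotypes only. `count_b` is the number
#' of copies of `allele_b` observed, `count_het` the number of heterozygotes.
#'
#' @param ds a `genotype_dataset`; alternatively supply raw counts via
#'   [allele_counts_raw()].
#' @param snp_id the SNP to count.
#' @param samples optional subset of sample IDs (default all).
#' @return an `allele_counts` object: list with `n_genotyped`, `count_b`,
#'   `count_het`.
#' @export
allele_counts <- function(ds, snp_id, samples = NULL) {
  j <- match(snp_id, ds$variants$snp_id)
  if (is.na(j)) stop("unknown snp_id: ", snp_id)
  g <- ds$genotypes[, j]
  if (!is.null(samples)) g <- g[resolve_index(samples, ds$samples, "sample")]
  g <- g[!is.na(g)]
  allele_counts_raw(length(g), sum(g), sum(g == 1L))
}

#' Construct allele counts directly
#'
#' @param n_genotyped number of diploid individuals with a non-missing genotype.
#' @param count_b copies of `allele_b` observed (may be fractional when derived
#'   from a frequency).
#' @param count_het heterozygous individuals (fractional allowed, e.g. the
#'   Hardy-Weinberg expectation `2 n p (1-p)`).
#' @return an `allele_counts` object.
#' @export
allele_counts_raw <- function(n_genotyped, count_b, count_het) {
  if (count_b > 2 * n_genotyped + 1e-9) stop("count_b exceeds 2 * n_genotyped")
  if (count_het > n_genotyped + 1e-9) stop("count_het exceeds n_genotyped")
  if (count_het > count_b + 1e-9 || count_het > 2 * n_genotyped - count_b + 1e-9) {
    stop("count_het incompatible with allele counts")
  }
  structure(list(n_genotyped = n_genotyped, count_b = count_b,
                 count_het = count_het),
            class = "allele_counts")
}

#' Allele counts from a frequency under Hardy-Weinberg proportions
#'
#' Convenience constructor for worked examples where only an allele frequency
#' is reported: heterozygosity is set to its Hardy-Weinberg expectation.
#'
#' @param p frequency of `allele_b`.
#' @param n number of diploid individuals.
#' @return an `allele_counts` object.
#' @export
allele_counts_from_freq <- function(p, n) {
  allele_counts_raw(n, 2 * n * p, 2 * n * p * (1 - p))
}

#' Per-SNP allele_b frequencies over a sample subset
#'
#' @param ds a `genotype_dataset`.
#' @param samples optional sample subset (IDs or index); default all.
#' @return numeric vector of frequencies (NaN where no genotypes observed).
#' @export
allele_freqs <- function(ds, samples = NULL) {
  g <- ds$genotypes
  if (!is.null(samples)) {
    g <- g[resolve_index(samples, ds$samples, "sample"), , drop = FALSE]
  }
  n <- colSums(!is.na(g))
  colSums(g, na.rm = TRUE) / (2 * n)
}
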