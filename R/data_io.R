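#' Construct a case-control genotype study
#'
#' Bundles a genotype matrix (individuals x SNPs, minor-allele counts
#' 0/1/2, `NA` for missing), the SNP identifiers and a binary phenotype
#' (1 = case, 0 = control) into a validated `genotype_study` object, the
#' unit on which all scans operate.
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns;
#'   entries 0, 1, 2 or `NA`.
#' @param snp_ids character vector of unique SNP identifiers, one per
#'   column.
#' @param phenotype integer/numeric vector of 0 (control) / 1 (case), one
#'   per row.
#' @return An object of class `genotype_study` with elements `genotypes`,
#'   `snp_ids`, `phenotype`.
#' @export
genotype_study <- function(genotypes, snp_ids, phenotype) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  snp_ids <- as.character(snp_ids)
  if (nrow(genotypes) != length(phenotype))
    stop("phenotype length (", length(phenotype),
         ") does not match genotype row count (", nrow(genotypes), ")")
  if (ncol(genotypes) != length(snp_ids))
    stop("snp_ids length does not match genotype column count")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  bad <- genotypes[!is.na(genotypes) & !(genotypes %in% 0:2)]
  if (length(bad))
    stop("genotype codes outside {0,1,2,NA}: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  if (!all(phenotype %in% 0:1))
    stop("phenotype must be coded 0 (control) / 1 (case)")
  if (!any(phenotype == 1) || !any(phenotype == 0))
    stop("study must contain at least one case and one control")
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, snp_ids = snp_ids,
                 phenotype = phenotype),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("genotype_study:", nrow(x$genotypes), "individuals (",
      sum(x$phenotype == 1), "cases /", sum(x$phenotype == 0),
      "controls ) x", ncol(x$genotypes), "SNPs\n")
  nm <- sum(is.na(x$genotypes))
  if (nm > 0) cat("  missing genotype calls:", nm, "\n")
  invisible(x)
}

MISSING_TOKENS <- c("-9", "NA")

#' Read a case-control genotype file
#'
#' Two text dialects are supported. `mdr_flat` is the tab-delimited MDR
#' community format: one header row of SNP ids with a final column named
#' `Class`, then one row per individual with genotype codes 0/1/2
#' (missing as `-9` or `NA`) and class 0/1. `plink_raw` is the
#' whitespace-delimited PLINK `--recode A` layout: columns FID, IID, PAT,
#' MAT, SEX, PHENOTYPE followed by one allele-dosage column per SNP;
#' phenotypes 1/2 are recoded to control/case, 0/1 accepted as-is.
#'
#' @param path path to the genotype file.
#' @param format one of `"mdr_flat"` (default) or `"plink_raw"`.
#' @return A [genotype_study()].
#' @export
read_genotypes <- function(path, format = c("mdr_flat", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mdr_flat") read_mdr_flat(path) else read_plink_raw(path)
}

read_mdr_flat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("genotype file must have a header and at least one individual: ",
         path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  ncols <- length(header)
  if (header[ncols] != "Class")
    stop("last header column must be 'Class', found '", header[ncols], "'")
  snp_ids <- header[-ncols]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != ncols)) {
    bad <- which(lens != ncols)[1]
    stop("line ", bad + 1L, ": expected ", ncols, " fields, found ",
         lens[bad])
  }
  m <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
  cls <- m[, ncols]
  if (!all(cls %in% c("0", "1")))
    stop("Class column must be 0/1, found: ",
         paste(unique(setdiff(cls, c("0", "1"))), collapse = ", "))
  g <- m[, -ncols, drop = FALSE]
  g[g %in% MISSING_TOKENS] <- NA
  if (!all(is.na(g) | g %in% c("0", "1", "2")))
    stop("genotype codes must be 0/1/2 or missing (-9/NA); found: ",
         paste(utils::head(setdiff(unique(g[!is.na(g)]), c("0", "1", "2")),
                           5), collapse = ", "))
  gm <- matrix(as.integer(g), nrow = nrow(g))
  genotype_study(gm, snp_ids, as.integer(cls))
}

read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-9"))
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)))
    stop("plink_raw file must carry columns ", paste(meta, collapse = ", "))
  snp_cols <- setdiff(names(df), meta)
  if (!length(snp_cols)) stop("no SNP columns found")
  ph <- df$PHENOTYPE
  if (all(ph %in% c(1, 2))) {
    ph <- as.integer(ph == 2)
  } else if (!all(ph %in% c(0, 1))) {
    stop("PHENOTYPE must be coded 1/2 (plink) or 0/1")
  }
  # strip plink's _<allele> suffix from SNP column names when present
  ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  if (anyDuplicated(ids)) ids <- snp_cols
  genotype_study(as.matrix(df[, snp_cols, drop = FALSE]), ids,
                 as.integer(ph))
}

#' Write a genotype study in the MDR flat dialect
#'
#' @param study a [genotype_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(study, path) {
  stopifnot(inherits(study, "genotype_study"))
  g <- study$genotypes
  gc <- matrix(as.character(g), nrow = nrow(g))
  gc[is.na(gc)] <- "-9"
  lines <- c(paste(c(study$snp_ids, "Class"), collapse = "\t"),
             vapply(seq_len(nrow(gc)), function(r) {
               paste(c(gc[r, ], study$phenotype[r]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP map (snp_id, chromosome, position)
#'
#' Tab-delimited with a header row naming the three columns; positions
#' are 1-based base-pair coordinates.
#'
#' @param path path to the map file.
#' @return data.frame with columns `snp_id`, `chromosome`, `position`.
#' @export
read_snp_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("SNP map must have columns ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$position))
  if (anyNA(pos) || any(pos != floor(pos)))
    stop("non-integer position in SNP map")
  if (any(pos < 1))
    stop("positions must be positive 1-based coordinates")
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id in SNP map: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  data.frame(snp_id = df$snp_id, chromosome = df$chromosome,
             position = as.integer(pos), stringsAsFactors = FALSE)
}

#' @rdname read_snp_map
#' @param snp_map data.frame as returned by `read_snp_map`.
#' @export
write_snp_map <- function(snp_map, path) {
  utils::write.table(snp_map[, c("snp_id", "chromosome", "position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED4 file
#'
#' BED intervals are 0-based half-open; they are converted at this
#' boundary to the 1-based inclusive coordinates used everywhere inside
#' the package (`start = bed_start + 1`, `end = bed_end`). Column 4
#' supplies the gene identifier.
#'
#' @param path path to the BED file.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(empty)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(rows) < 4))
    stop("BED line with fewer than 4 fields (name required in column 4)")
  chrom <- vapply(rows, `[[`, character(1), 1)
  bstart <- as.numeric(vapply(rows, `[[`, character(1), 2))
  bend <- as.numeric(vapply(rows, `[[`, character(1), 3))
  name <- vapply(rows, `[[`, character(1), 4)
  if (anyNA(bstart) || anyNA(bend)) stop("non-numeric BED coordinates")
  if (any(bstart >= bend))
    stop("BED interval with start >= end (half-open intervals must be ",
         "non-empty)")
  if (anyDuplicated(name))
    stop("duplicate gene_id in annotation: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  data.frame(gene_id = name, chromosome = chrom,
             start = as.integer(bstart + 1), end = as.integer(bend),
             stringsAsFactors = FALSE)
}

#' @rdname read_gene_annotation
#' @param genes data.frame as returned by `read_gene_annotation`.
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- data.frame(genes$chromosome, genes$start - 1L, genes$end,
                    genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member gene symbols,
#' tab-delimited (the MSigDB layout). Duplicate members within a line
#' are deduplicated; a description equal to `BP`, `CC` or `MF` is taken
#' as the Gene Ontology branch, otherwise the branch is `unspecified`.
#'
#' @param path path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors, in file order) and `branch` (named character).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    bad <- which(lengths(fields) < 3)[1]
    stop("GMT line ", bad, ": fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT file")
  branch <- ifelse(desc %in% c("BP", "CC", "MF"), desc, "unspecified")
  names(branch) <- nm
  structure(list(sets = sets[nm], branch = branch),
            class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @param collection a `gene_set_collection`.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- collection$branch[nm]
  desc[is.na(desc) | desc == "unspecified"] <- "na"
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, sizes ",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}
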