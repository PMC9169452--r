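# Reading, validating and joining GWAS summary-statistic tables.
#
# Canonical in-memory form: a data.frame with columns
#   snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n
# Canonical on-disk form: header-bearing tab-delimited text with columns
#   SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N

.canonical_fields <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pval", "n")

.default_column_map <- c(SNP = "snp_id", CHR = "chrom", POS = "pos",
                         EA = "effect_allele", OA = "other_allele",
                         EAF = "eaf", BETA = "beta", SE = "se",
                         P = "pval", N = "n")

#' Default column map for summary-statistics files
#'
#' Maps the canonical on-disk headers (`SNP`, `CHR`, `POS`, `EA`, `OA`,
#' `EAF`, `BETA`, `SE`, `P`, `N`) to the canonical in-memory field names.
#' Public downloads name these columns differently (e.g. `rsid`,
#' `effect_allele_frequency`); pass a modified copy of this vector to
#' [read_sumstats()] to absorb such dialects.
#'
#' @return Named character vector: names are file headers, values canonical
#'   field names.
#' @export
default_column_map <- function() .default_column_map

# strict numeric coercion: "" and NA pass through, junk raises with row context
.parse_numeric <- function(x, field, required = FALSE) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) %in% c("", "NA", ".")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                 x[bad[1]], field, bad[1]), call. = FALSE)
  if (required && anyNA(out))
    stop(sprintf("missing value in required column '%s' at data row %d",
                 field, which(is.na(out))[1]), call. = FALSE)
  out
}

.validate_sumstats <- function(df, context = "sumstats") {
  fail <- function(rows, msg) {
    stop(sprintf("%s: %s (data row%s %s)", context, msg,
                 if (length(rows) > 1) "s" else "",
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  alleles_ok <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  bad <- which(!alleles_ok(df$effect_allele) | !alleles_ok(df$other_allele))
  if (length(bad))
    fail(bad, "alleles must be single bases A/C/G/T (indels and multi-allelic variants are not supported)")
  bad <- which(df$effect_allele == df$other_allele)
  if (length(bad)) fail(bad, "effect and other allele are identical")
  bad <- which(is.na(df$beta))
  if (length(bad)) fail(bad, "missing beta")
  bad <- which(is.na(df$se) | df$se <= 0)
  if (length(bad)) fail(bad, "se must be > 0")
  bad <- which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  if (length(bad)) fail(bad, "eaf outside [0, 1]")
  bad <- which(!is.na(df$pval) & (df$pval <= 0 | df$pval > 1))
  if (length(bad)) fail(bad, "p-value outside (0, 1]")
  bad <- which(!is.na(df$pos) & df$pos < 1)
  if (length(bad)) fail(bad, "position must be >= 1 (1-based)")
  invisible(df)
}

#' Read a GWAS summary-statistics table
#'
#' Reads header-bearing tab-delimited summary statistics into the canonical
#' form used throughout the package. Alleles are upper-cased; chromosome
#' labels are kept as strings with any `"chr"` prefix stripped; rows that
#' violate the record invariants (non-ACGT or identical alleles, `se <= 0`,
#' `eaf` outside \[0, 1\], `p` outside (0, 1\]) are rejected with a row-level
#' diagnostic rather than silently dropped.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping file headers to canonical
#'   field names (see [default_column_map()]). Headers not in the map are
#'   ignored. The fields `snp_id`, `effect_allele`, `other_allele`, `beta`
#'   and `se` must be mapped and present; the rest are optional and recorded
#'   as `NA` when absent.
#' @return A data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   one row per input data row, in file order.
#' @seealso [write_sumstats()], [join_instruments()]
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  hdr <- names(raw)
  mapped <- column_map[names(column_map) %in% hdr]
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_req <- setdiff(required, unname(mapped))
  if (length(missing_req)) {
    want <- names(column_map)[column_map %in% missing_req]
    label <- if (length(want)) want else missing_req
    stop("summary-statistics format error: required column(s) missing from ",
         "header or column map: ", paste(label, collapse = ", "),
         call. = FALSE)
  }
  get <- function(field) {
    hit <- names(mapped)[mapped == field]
    if (length(hit)) raw[[hit[1]]] else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(
    snp_id        = get("snp_id"),
    chrom         = sub("^chr", "", get("chrom"), ignore.case = TRUE),
    pos           = .parse_numeric(get("pos"), "pos"),
    effect_allele = toupper(trimws(get("effect_allele"))),
    other_allele  = toupper(trimws(get("other_allele"))),
    eaf           = .parse_numeric(get("eaf"), "eaf"),
    beta          = .parse_numeric(get("beta"), "beta", required = TRUE),
    se            = .parse_numeric(get("se"), "se", required = TRUE),
    pval          = .parse_numeric(get("pval"), "pval"),
    n             = .parse_numeric(get("n"), "n"),
    stringsAsFactors = FALSE
  )
  .validate_sumstats(df, context = basename(path))
  df
}

#' Write a summary-statistics table in the canonical on-disk format
#'
#' @param df Canonical summary-statistics data.frame (as returned by
#'   [read_sumstats()]).
#' @param path Output path; tab-delimited with the canonical header
#'   `SNP CHR POS EA OA EAF BETA SE P N`.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = df$eaf, BETA = df$beta, SE = df$se,
                    P = df$pval, N = df$n, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Construct an instrument set
#'
#' An instrument set is a summary-statistics table of independent SNPs
#' robustly associated with an exposure trait (here, an adult adiposity
#' trait), with the adiposity-raising allele conventionally recorded as the
#' effect allele, plus a label and the trait's units.
#'
#' @param records Canonical summary-statistics data.frame of per-SNP adult
#'   trait effects.
#' @param name Label for the set (e.g. `"favorable-adiposity-14"`).
#' @param trait_units Free-text units of the exposure trait.
#' @return `records` with class `instrument_set` and attributes `name` and
#'   `trait_units`; `snp_id` must be unique.
#' @export
instrument_set <- function(records, name = "instruments",
                           trait_units = "SD") {
  .validate_sumstats(records, context = name)
  dup <- unique(records$snp_id[duplicated(records$snp_id)])
  if (length(dup))
    stop("integrity error: duplicate snp_id in instrument set '", name,
         "': ", paste(dup, collapse = ", "), call. = FALSE)
  structure(records, class = c("instrument_set", "data.frame"),
            name = name, trait_units = trait_units)
}

#' Join an instrument set to an outcome summary-statistics table
#'
#' Pairs every instrument SNP with its record in the outcome table, keyed by
#' `snp_id`. Instruments absent from the outcome table are reported in a
#' missing-list, never silently dropped; a duplicated `snp_id` in either
#' input is an integrity error.
#'
#' @param instruments Instrument set (or plain canonical data.frame).
#' @param outcome Canonical summary-statistics data.frame for the outcome
#'   trait.
#' @return List with elements `pairs` (a data.frame holding the instrument
#'   record columns prefixed `exposure_` and the outcome record columns
#'   prefixed `outcome_`, one row per instrument found, in instrument order)
#'   and `missing` (character vector of instrument SNP ids absent from the
#'   outcome table).
#' @export
join_instruments <- function(instruments, outcome) {
  for (nm in c("instruments", "outcome")) {
    df <- if (nm == "instruments") instruments else outcome
    dup <- unique(df$snp_id[duplicated(df$snp_id)])
    if (length(dup))
      stop("integrity error: duplicate snp_id in ", nm, ": ",
           paste(dup, collapse = ", "), call. = FALSE)
  }
  hit <- instruments$snp_id %in% outcome$snp_id
  missing <- instruments$snp_id[!hit]
  if (!any(hit))
    stop("empty join: no instrument SNPs found in the outcome table",
         call. = FALSE)
  ins <- as.data.frame(instruments)[hit, , drop = FALSE]
  out <- as.data.frame(outcome)[match(ins$snp_id, outcome$snp_id), ,
                                drop = FALSE]
  pairs <- cbind(
    snp_id = ins$snp_id,
    setNames(ins[.canonical_fields[-1]],
             paste0("exposure_", .canonical_fields[-1])),
    setNames(out[.canonical_fields[-1]],
             paste0("outcome_", .canonical_fields[-1]))
  )
  rownames(pairs) <- NULL
  list(pairs = pairs, missing = missing)
}
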