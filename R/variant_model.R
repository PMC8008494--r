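# Domain types and table IO for BRCA2 DNA-binding-domain missense variants.
# Residue numbering is 1-based against the NP_000050.2 protein (3418 aa);
# coding names (NM_000059.3) are carried as opaque labels only.

#' @keywords internal
AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

#' @keywords internal
BRCA2_PROTEIN_LENGTH <- 3418L

#' Five-tier classification labels, benign to pathogenic
#'
#' @return Character vector `c("B", "LB", "VUS", "LP", "P")`.
#' @export
classification_tiers <- function() c("B", "LB", "VUS", "LP", "P")

#' Parse a protein-level HGVS missense name
#'
#' Accepts the `p.<Aaa><pos><Aaa>` shorthand with three-letter amino-acid
#' codes (e.g. `"p.Asp2723His"`). Nonsense (`Ter`) and synonymous changes are
#' rejected: only missense substitutions occur in this analysis.
#'
#' @param text Character vector of protein HGVS strings.
#' @return A data.frame with columns `ref_aa`, `residue`, `alt_aa`.
#' @examples
#' parse_protein_hgvs("p.Asp2723His")
#' @export
parse_protein_hgvs <- function(text) {
  stopifnot(is.character(text))
  m <- regmatches(text, regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed protein HGVS string: ", paste(text[bad], collapse = ", "))
  }
  ref <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  alt <- vapply(m, `[[`, "", 4L)
  unknown <- setdiff(unique(c(ref, alt)), AA_THREE)
  if (length(unknown) > 0) {
    stop("unknown amino-acid code: ", paste(unknown, collapse = ", "))
  }
  syn <- ref == alt
  if (any(syn)) {
    stop("synonymous change is not a missense variant: ",
         paste(text[syn], collapse = ", "))
  }
  data.frame(ref_aa = ref, residue = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Format a parsed missense variant back to protein HGVS
#'
#' Inverse of [parse_protein_hgvs()]: `format(parse(x)) == x`.
#'
#' @param ref_aa,alt_aa Three-letter amino-acid codes.
#' @param residue Integer residue position (1-based).
#' @return Character vector of `p.` names.
#' @export
format_protein_hgvs <- function(ref_aa, residue, alt_aa) {
  stopifnot(all(ref_aa %in% AA_THREE), all(alt_aa %in% AA_THREE),
            all(residue >= 1))
  sprintf("p.%s%d%s", ref_aa, as.integer(residue), alt_aa)
}

#' Default BRCA2 domain map
#'
#' Carries only the boundaries the analysis relies on: the DNA-binding domain
#' (DBD, residues 2481-3186), the OB2 fold (2804-3054) and the Tower
#' sub-domain within OB2 (2838-2962). Helical/OB1/OB3 boundaries are not part
#' of the default map and can be supplied by the caller. Intervals are
#' 1-based inclusive and must be nested or disjoint.
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
default_domain_map <- function() {
  data.frame(
    label = c("DBD", "OB2", "Tower"),
    start = c(2481L, 2804L, 2838L),
    end   = c(3186L, 3054L, 2962L),
    stringsAsFactors = FALSE
  )
}

# Intervals must be pairwise nested or disjoint; anything else is a
# configuration error (an ambiguous "innermost" label).
validate_domain_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("label", "start", "end") %in% names(map)))
  if (any(map$start > map$end)) stop("domain map interval with start > end")
  n <- nrow(map)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- map[i, ]; b <- map[j, ]
        disjoint <- a$end < b$start || b$end < a$start
        nested <- (a$start <= b$start && b$end <= a$end) ||
          (b$start <= a$start && a$end <= b$end)
        if (!disjoint && !nested) {
          stop("domain map intervals overlap without nesting: ",
               a$label, " and ", b$label)
        }
      }
    }
  }
  invisible(map)
}

#' Annotate a residue with its most specific enclosing domain
#'
#' Returns the innermost (narrowest) interval containing the residue, or
#' `"outside-DBD"` when the residue falls in no mapped interval.
#'
#' @param residue Integer vector of 1-based residue positions.
#' @param map Domain map as from [default_domain_map()].
#' @return Character vector of labels.
#' @examples
#' annotate_domain(2900) # "Tower"
#' @export
annotate_domain <- function(residue, map = default_domain_map()) {
  stopifnot(all(residue >= 1))
  validate_domain_map(map)
  width <- map$end - map$start
  vapply(as.integer(residue), function(r) {
    hit <- map$start <= r & r <= map$end
    if (!any(hit)) return("outside-DBD")
    map$label[hit][which.min(width[hit])]
  }, character(1))
}

#' Build variant records from protein HGVS names
#'
#' @param hgvs_p Character vector of protein HGVS names.
#' @param hgvs_c Optional coding names (opaque labels), recycled or NA.
#' @param map Domain map used for annotation.
#' @return data.frame with columns `hgvs_c`, `hgvs_p`, `residue`, `ref_aa`,
#'   `alt_aa`, `domain`.
#' @export
variant_records <- function(hgvs_p, hgvs_c = NA_character_,
                            map = default_domain_map()) {
  parsed <- parse_protein_hgvs(hgvs_p)
  if (any(parsed$residue > BRCA2_PROTEIN_LENGTH)) {
    stop("residue beyond BRCA2 protein length (", BRCA2_PROTEIN_LENGTH, ")")
  }
  data.frame(
    hgvs_c = rep_len(hgvs_c, length(hgvs_p)),
    hgvs_p = hgvs_p,
    residue = parsed$residue,
    ref_aa = parsed$ref_aa,
    alt_aa = parsed$alt_aa,
    domain = annotate_domain(parsed$residue, map),
    stringsAsFactors = FALSE
  )
}

#' Read a tab-separated variant table
#'
#' Requires a `hgvs_p` header column; `residue` and `domain` are recomputed
#' from the name (and cross-checked when present). Duplicate `hgvs_p` entries
#' are flagged with a warning, not dropped.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param map Domain map used for annotation.
#' @return data.frame of variant records, row order preserved.
#' @export
read_variant_table <- function(path, map = default_domain_map()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"hgvs_p" %in% names(df)) {
    stop("variant table is missing required column 'hgvs_p': ", path)
  }
  if (nrow(df) == 0) {
    return(variant_records(character(0))[0, ])
  }
  dup <- duplicated(df$hgvs_p)
  if (any(dup)) {
    warning("duplicate hgvs_p entries: ",
            paste(unique(df$hgvs_p[dup]), collapse = ", "))
  }
  rec <- variant_records(df$hgvs_p,
                         hgvs_c = if ("hgvs_c" %in% names(df)) df$hgvs_c else NA,
                         map = map)
  if ("residue" %in% names(df) && any(df$residue != rec$residue)) {
    stop("residue column disagrees with hgvs_p for: ",
         paste(df$hgvs_p[df$residue != rec$residue], collapse = ", "))
  }
  extra <- setdiff(names(df), names(rec))
  cbind(rec, df[, extra, drop = FALSE])
}

#' Write a variant table as TSV
#'
#' @param records data.frame of variant records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Frozen md5 of the packaged non-functional-variant table; guards against a
# silently edited fixture.
TABLE1_MD5 <- "01e6cdf137f1b11cb4606f982328c979"

#' Path to the packaged table of 90 non-functional variants
#'
#' @return File path inside the installed package.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "brca2hdr", mustWork = TRUE)
}

#' Read the packaged non-functional-variant table
#'
#' The table transcribes, for each of the 90 variants called non-functional
#' by the HDR assay: the HDR score and its upper 95% credible bound, the
#' applied ACMG/AMP evidence codes (PS3; PM1 or PM1_supporting; PM5; PP1 or
#' PP1_moderate; PM3 or PM3_strong or BP2; PP3/BP4/inconclusive; BA1/BS1/
#' PM2_supporting), and the classification before and after functional
#' evidence (`N/O` = not observed by the testing laboratory).
#'
#' Note on sub-domain counts: eight of these variants fall in the OB2 region
#' 2804-3054 (residues 2819 x2, 2824, 3003, 3006, 3028, 3052 x2), while the
#' accompanying prose reports seven non-functional OB2 variants; the table is
#' transcribed as printed and no seven-count is asserted anywhere.
#'
#' @param path Path to the table; defaults to the packaged fixture.
#' @param verify_checksum Error on checksum mismatch (default TRUE for the
#'   packaged file; set FALSE for a user-supplied table).
#' @return data.frame with one row per variant.
#' @export
read_table1 <- function(path = table1_path(), verify_checksum = TRUE) {
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE1_MD5)) {
      stop("fixture checksum mismatch for ", path,
           " (got ", md5, ", expected ", TABLE1_MD5, ")")
    }
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = character(0))
  stopifnot(all(c("hgvs_p", "hdr_score", "hdr_upper_ci", "ps3",
                  "before_class", "final_class") %in% names(df)))
  df
}
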