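# Amino-acid code tables and HGVS protein (p.) parsing.
#
# Only the subset of the HGVS protein grammar that somatic small-variant
# reporting actually produces is supported: substitutions (incl. nonsense),
# in-frame deletions / insertions / delins, duplications and frameshifts.
# Inversions, extensions and mosaic/allele syntax are out of scope.

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))

#' Convert a three-letter amino-acid code to the one-letter code
#'
#' Hotspot lists and most genomic databases key variants by the one-letter
#' protein shorthand, while HGVS reporting mandates the three-letter code, so
#' this conversion sits on the critical path of every hotspot lookup. It is
#' strict: the classic slips (D/N read as "A", E read as "G", W read as "T")
#' are impossible because anything but an exact three-letter code is an error.
#'
#' @param code3 character vector of three-letter residue codes
#'   (`"Ala"` ... `"Val"`, plus `"Ter"` for a stop codon).
#' @return character vector of IUPAC one-letter codes (`"*"` for `Ter`).
#' @examples
#' aa_three_to_one(c("Val", "Trp", "Ter"))  # "V" "W" "*"
#' @seealso [aa_one_to_three()], [shorthand()]
#' @export
aa_three_to_one <- function(code3) {
  out <- AA_THREE_TO_ONE[code3]
  if (anyNA(out)) {
    stop("unknown three-letter amino-acid code: ",
         paste(unique(code3[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Convert a one-letter amino-acid code to the three-letter code
#'
#' @param code1 character vector of one-letter residue codes (`"*"` allowed).
#' @return character vector of three-letter codes.
#' @export
aa_one_to_three <- function(code1) {
  out <- AA_ONE_TO_THREE[code1]
  if (anyNA(out)) {
    stop("unknown one-letter amino-acid code: ",
         paste(unique(code1[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

PROTEIN_KINDS <- c("substitution", "inframe_del", "inframe_ins",
                   "inframe_delins", "frameshift", "nonsense", "duplication")

new_protein_change <- function(ref_aa, position, end_position = NA_integer_,
                               alt_aa = NA_character_, kind,
                               end_ref_aa = NA_character_,
                               ins_seq = NA_character_,
                               fs_alt = NA_character_, fs_term = NA_integer_,
                               parenthesised = TRUE) {
  stopifnot(kind %in% PROTEIN_KINDS)
  if (!is.na(end_position) && end_position < position) {
    stop("end_position must be >= position")
  }
  if (kind == "nonsense" && !identical(alt_aa, "*")) {
    stop("kind 'nonsense' requires alt_aa '*'")
  }
  structure(
    list(ref_aa = ref_aa, position = as.integer(position),
         end_position = as.integer(end_position), alt_aa = alt_aa,
         kind = kind, end_ref_aa = end_ref_aa, ins_seq = ins_seq,
         fs_alt = fs_alt, fs_term = as.integer(fs_term),
         parenthesised = isTRUE(parenthesised)),
    class = "protein_change"
  )
}

AA3 <- "(Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val|Ter)"

#' Parse an HGVS protein change (three-letter code)
#'
#' Turns strings such as `"p.(Leu858Arg)"`, `"p.(Asn140Metfs*5)"` or
#' `"p.(Ser566_Glu577del)"` into a structured `protein_change` object so that
#' hotspot matching can be done on positions and residues rather than on raw
#' text. Parsing is strict: a string that does not match the supported grammar
#' is an error naming the offending token — a malformed variant must never
#' silently drift into the VUS pool.
#'
#' @param protein_hgvs a single HGVS p. string, three-letter residue codes,
#'   optionally wrapped in parentheses (predicted consequence).
#' @return an object of class `protein_change` with fields `ref_aa`,
#'   `position`, `end_position`, `alt_aa`, `kind` (one of substitution,
#'   inframe_del, inframe_ins, inframe_delins, frameshift, nonsense,
#'   duplication) plus rendering detail (`end_ref_aa`, `ins_seq`, `fs_alt`,
#'   `fs_term`, `parenthesised`).
#' @examples
#' parse_protein_change("p.(Leu858Arg)")
#' parse_protein_change("p.(Ser1870*)")$kind     # "nonsense"
#' parse_protein_change("p.(Asn140Metfs*5)")$kind  # "frameshift"
#' @export
parse_protein_change <- function(protein_hgvs) {
  stopifnot(is.character(protein_hgvs), length(protein_hgvs) == 1L)
  raw <- trimws(protein_hgvs)
  body <- sub("^p\\.", "", raw)
  parens <- grepl("^\\(.*\\)$", body)
  if (parens) body <- sub("^\\((.*)\\)$", "\\1", body)

  m <- function(pattern) {
    r <- regexec(paste0("^", pattern, "$"), body)
    g <- regmatches(body, r)[[1]]
    if (length(g)) g else NULL
  }
  one <- function(x) aa_three_to_one(x)

  # frameshift: Asn140Metfs*5, Ser149Phefs*32, Lys120fs
  g <- m(paste0(AA3, "([0-9]+)", AA3, "?fs(\\*([0-9]+|\\?))?"))
  if (!is.null(g)) {
    fs_alt <- if (nzchar(g[4])) one(g[4]) else NA_character_
    fs_term <- if (nzchar(g[6]) && g[6] != "?") as.integer(g[6]) else NA_integer_
    return(new_protein_change(one(g[2]), as.integer(g[3]), kind = "frameshift",
                              fs_alt = fs_alt, fs_term = fs_term,
                              parenthesised = parens))
  }

  # substitution / nonsense: Leu858Arg, Ser1870*, Ser1870Ter
  g <- m(paste0(AA3, "([0-9]+)(", AA3, "|\\*)"))
  if (!is.null(g)) {
    alt <- if (g[4] == "*") "*" else one(g[4])
    kind <- if (alt == "*") "nonsense" else "substitution"
    return(new_protein_change(one(g[2]), as.integer(g[3]), alt_aa = alt,
                              kind = kind, parenthesised = parens))
  }

  # range forms: del / dup / ins / delins
  g <- m(paste0(AA3, "([0-9]+)(_", AA3, "([0-9]+))?(del|dup)"))
  if (!is.null(g)) {
    kind <- if (g[7] == "dup") "duplication" else "inframe_del"
    end_pos <- if (nzchar(g[6])) as.integer(g[6]) else NA_integer_
    end_ref <- if (nzchar(g[5])) one(g[5]) else NA_character_
    return(new_protein_change(one(g[2]), as.integer(g[3]),
                              end_position = end_pos, kind = kind,
                              end_ref_aa = end_ref, parenthesised = parens))
  }
  g <- m(paste0(AA3, "([0-9]+)(_", AA3, "([0-9]+))?delins((", AA3, ")+)"))
  if (!is.null(g)) {
    ins <- paste(one(split_aa3(g[7])), collapse = "")
    end_pos <- if (nzchar(g[6])) as.integer(g[6]) else NA_integer_
    end_ref <- if (nzchar(g[5])) one(g[5]) else NA_character_
    return(new_protein_change(one(g[2]), as.integer(g[3]),
                              end_position = end_pos, kind = "inframe_delins",
                              end_ref_aa = end_ref, ins_seq = ins,
                              parenthesised = parens))
  }
  g <- m(paste0(AA3, "([0-9]+)_", AA3, "([0-9]+)ins((", AA3, ")+)"))
  if (!is.null(g)) {
    ins <- paste(one(split_aa3(g[6])), collapse = "")
    return(new_protein_change(one(g[2]), as.integer(g[3]),
                              end_position = as.integer(g[5]),
                              kind = "inframe_ins", end_ref_aa = one(g[4]),
                              ins_seq = ins, parenthesised = parens))
  }

  stop("cannot parse HGVS protein change: '", raw, "'")
}

split_aa3 <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Render a `protein_change` back to HGVS three-letter notation
#'
#' Inverse of [parse_protein_change()]; used for reports, which must carry the
#' three-letter form.
#'
#' @param change a `protein_change` object.
#' @return a single HGVS p. string.
#' @export
render_protein_change <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  three <- function(x) aa_one_to_three(x)
  span <- function() {
    s <- paste0(three(change$ref_aa), change$position)
    if (!is.na(change$end_position)) {
      s <- paste0(s, "_", three(change$end_ref_aa), change$end_position)
    }
    s
  }
  body <- switch(change$kind,
    substitution = paste0(three(change$ref_aa), change$position,
                          three(change$alt_aa)),
    nonsense = paste0(three(change$ref_aa), change$position, "*"),
    frameshift = paste0(three(change$ref_aa), change$position,
                        if (!is.na(change$fs_alt)) three(change$fs_alt) else "",
                        "fs",
                        if (!is.na(change$fs_term))
                          paste0("*", change$fs_term) else ""),
    inframe_del = paste0(span(), "del"),
    duplication = paste0(span(), "dup"),
    inframe_ins = paste0(span(), "ins",
                         paste(three(strsplit(change$ins_seq, "")[[1]]),
                               collapse = "")),
    inframe_delins = paste0(span(), "delins",
                            paste(three(strsplit(change$ins_seq, "")[[1]]),
                                  collapse = ""))
  )
  if (change$parenthesised) body <- paste0("(", body, ")")
  paste0("p.", body)
}

#' One-letter shorthand of a protein substitution
#'
#' The compact `L858R`-style notation used to query hotspot lists and familiar
#' to clinicians. Only point changes have a shorthand; indels and frameshifts
#' are matched structurally against hotspot entries, never by shorthand, and
#' are rejected here.
#'
#' @param change a `protein_change` of kind `substitution` or `nonsense`.
#' @return a string `"<ref><pos><alt>"`, e.g. `"V617F"` or `"S1870*"`.
#' @examples
#' shorthand(parse_protein_change("p.(Leu858Arg)"))  # "L858R"
#' @export
shorthand <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  if (!change$kind %in% c("substitution", "nonsense")) {
    stop("no one-letter shorthand for kind '", change$kind,
         "'; indels are matched structurally")
  }
  paste0(change$ref_aa, change$position, change$alt_aa)
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", render_protein_change(x), " [", x$kind, "]\n",
      sep = "")
  invisible(x)
}

#' @export
format.protein_change <- function(x, ...) render_protein_change(x)
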