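#' Lipid class registry
#'
#' The set of shotgun-lipidomics class tokens the parser recognises, with
#' structural flags used downstream. The default registry covers the classes
#' monitored in a typical direct-infusion glycerophospholipid /
#' neutral-lipid / sphingolipid panel: cholesteryl esters (CE), di- and
#' triacylglycerols (DAG, TAG), the diacyl glycerophospholipids and their
#' ether (O-) and lyso (L) variants, cardiolipin (CL), and the sphingolipids
#' Cer, HexCer and SM.
#'
#' The registry is data, not code: pass a modified tibble (same columns) as
#' the `registry` argument of [parse_species()] to extend or restrict the
#' accepted classes.
#'
#' @return A tibble with columns `code`, `is_lyso`, `is_ether`,
#'   `is_sphingolipid`, `is_sterol_ester`.
#' @export
#' @examples
#' lipid_class_registry()
lipid_class_registry <- function() {
  code <- c(
    "CE", "DAG", "TAG",
    "PC", "PC O-", "PE", "PE O-", "PS", "PI", "PA", "PG", "CL",
    "LPA", "LPC", "LPC O-", "LPE", "LPE O-", "LPI", "LPS",
    "Cer", "HexCer", "SM"
  )
  # lyso = the single-chain glycerophospholipids (leading "L"); CL is
  # cardiolipin, not lyso
  tibble::tibble(
    code = code,
    is_lyso = startsWith(code, "L"),
    is_ether = endsWith(code, "O-"),
    is_sphingolipid = code %in% c("Cer", "HexCer", "SM"),
    is_sterol_ester = code == "CE"
  )
}

parse_error <- function(kind, name, msg) {
  structure(
    class = c(paste0("lipid_parse_error_", kind), "lipid_parse_error",
              "error", "condition"),
    list(message = sprintf("%s [offending name: '%s']", msg, name),
         call = NULL, name = name)
  )
}

#' Parse lipid shorthand species names
#'
#' Parses names of the form `"<CLASS> <C>:<D>[;<suffix>]"`, e.g. `"LPE 22:6"`
#' or `"PE O-38:5"`, into structural features: class token, total fatty-acyl
#' carbons and total C=C double bonds summed over chains. The class token is
#' matched greedily against the registry (longest token first), so
#' `"LPE O-22:1"` parses as the ether-lyso class `LPE O-`, never as `LPE`.
#' For ether classes both `"PE O-38:5"` and `"PE O- 38:5"` are accepted; the
#' space-free form is emitted by [format_species()]. An optional `";n"`
#' suffix (sphingolipid hydroxylation field) is stored verbatim in
#' `extra_suffix` and ignored by all statistics.
#'
#' @param names Character vector of shorthand species names.
#' @param registry Class registry tibble, see [lipid_class_registry()].
#' @return A tibble with one row per name: `raw_name`, `class_code`,
#'   `is_lyso`, `is_ether`, `is_sphingolipid`, `is_sterol_ester`,
#'   `total_carbons`, `total_double_bonds`, `extra_suffix`.
#' @export
#' @examples
#' parse_species(c("LPE 22:6", "PC 34:0", "PE O-38:5"))
parse_species <- function(names, registry = lipid_class_registry()) {
  if (length(names) == 0L) {
    stop("no species names supplied")
  }
  stopifnot(is.character(names))
  if (anyNA(names) || any(!nzchar(names))) {
    stop(parse_error("empty", "", "empty or missing species name"))
  }
  codes <- registry$code[order(-nchar(registry$code), registry$code)]

  n <- length(names)
  class_code <- character(n)
  carbons <- integer(n)
  dbs <- integer(n)
  suffix <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    nm <- names[[i]]
    hit <- NA_character_
    rest <- NA_character_
    for (code in codes) {
      if (startsWith(nm, code)) {
        tail <- substring(nm, nchar(code) + 1L)
        # a token ending in "O-" may abut the C:D field; otherwise require
        # a separating space
        if (endsWith(code, "O-")) {
          tail <- sub("^ ", "", tail)
        } else {
          if (!startsWith(tail, " ")) next
          tail <- substring(tail, 2L)
        }
        hit <- code
        rest <- tail
        break
      }
    }
    if (is.na(hit)) {
      stop(parse_error("unknown_class", nm, "unknown lipid class token"))
    }
    m <- regmatches(rest, regexec("^([0-9]+):([0-9]+)(;.*)?$", rest))[[1]]
    if (length(m) == 0L) {
      stop(parse_error("malformed_cd", nm,
                       "malformed carbons:double-bonds field"))
    }
    cc <- as.integer(m[2])
    dd <- as.integer(m[3])
    if (is.na(cc) || is.na(dd) || cc < 1L || dd < 0L || dd >= cc) {
      stop(parse_error("bad_counts", nm,
                       "carbon/double-bond counts out of range"))
    }
    class_code[i] <- hit
    carbons[i] <- cc
    dbs[i] <- dd
    if (!is.na(m[4]) && nzchar(m[4])) suffix[i] <- m[4]
  }

  info <- registry[match(class_code, registry$code), ]
  tibble::tibble(
    raw_name = names,
    class_code = class_code,
    is_lyso = info$is_lyso,
    is_ether = info$is_ether,
    is_sphingolipid = info$is_sphingolipid,
    is_sterol_ester = info$is_sterol_ester,
    total_carbons = carbons,
    total_double_bonds = dbs,
    extra_suffix = suffix
  )
}

#' Format parsed species back to shorthand
#'
#' Inverse of [parse_species()]: emits `"<CLASS> <C>:<D>"` with the
#' space-free dialect for ether classes (`"PE O-38:5"`), re-appending any
#' stored suffix, so `format_species(parse_species(x))` round-trips every
#' registry-conformant name in canonical form.
#'
#' @param sp Tibble as returned by [parse_species()].
#' @return Character vector of shorthand names.
#' @export
format_species <- function(sp) {
  sep <- ifelse(endsWith(sp$class_code, "O-"), "", " ")
  suf <- ifelse(is.na(sp$extra_suffix), "", sp$extra_suffix)
  paste0(sp$class_code, sep, sp$total_carbons, ":", sp$total_double_bonds, suf)
}

#' Is a species saturated?
#'
#' A species is saturated iff it carries no C=C double bond in any acyl
#' chain (total double bonds equal to zero). Drives the
#' saturated/unsaturated partition of the LPE class.
#'
#' @param sp Tibble from [parse_species()], or an integer vector of total
#'   double-bond counts.
#' @return Logical vector.
#' @export
#' @examples
#' is_saturated(parse_species(c("LPE 18:0", "LPE 18:1")))
is_saturated <- function(sp) {
  db <- if (is.data.frame(sp)) sp$total_double_bonds else sp
  stopifnot(is.numeric(db), all(db >= 0))
  db == 0
}
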