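# Species token grammar: parsing the ion/molecule notation used in CQD
# selectivity tables ("Fe^3+", "Cr2O7^2-", "NH4^+", "glucose", ...) into a
# canonical chemical identity.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Metal oxoanions that are tallied under the oxidation state of their metal
# centre: a dichromate or chromate challenge is a Cr(VI) challenge.
OXOANION_STATES <- list(
  CR2O7 = list(element = "Cr", state = 6L),
  CRO4  = list(element = "Cr", state = 6L),
  MNO4  = list(element = "Mn", state = 7L),
  VO4   = list(element = "V",  state = 5L),
  MOO4  = list(element = "Mo", state = 6L),
  WO4   = list(element = "W",  state = 6L),
  ASO4  = list(element = "As", state = 5L),
  SEO4  = list(element = "Se", state = 6L)
)

ROMAN <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")

roman_numeral <- function(n) {
  stopifnot(n >= 1, n <= 10)
  ROMAN[n]
}

cqd_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cqd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Parse one species token
#'
#' Parses a species token as printed in a selectivity table (for example
#' `"Fe^3+"`, `"Cr2O7^2-"`, `"NH4^+"`, `"glucose"`) into a canonical chemical
#' identity.  Charge markers may be written `^3+`, `^+3`, `^1+` or as a bare
#' trailing sign (`"Mn+"`); Unicode minus signs and subscript underscores
#' (`"Cr_2_O_7_^2−^"`) are accepted.  Metal oxoanions whose metal centre has a
#' tabulated oxidation state canonicalize to that state, so dichromate and
#' chromate both map to `Cr(VI)` and merge with the cationic notation
#' `"Cr^6+"`.  Anything that is neither an element nor a chemical formula is
#' treated as an organic/neutral molecule keyed by its lower-cased name.
#'
#' @param token Character scalar, the species as printed.
#' @return An object of class `chem_species`: a list with fields `raw_token`,
#'   `element` (`""` for molecules and polyatomic non-metal ions), `charge`,
#'   `oxidation_state` (`NA` when not applicable), `kind` (one of `"cation"`,
#'   `"anion"`, `"molecule"`, `"radical"`) and `canonical_id`.
#' @examples
#' parse_species_token("Fe^3+")$canonical_id    # "Fe(III)"
#' parse_species_token("Cr2O7^2-")$canonical_id # "Cr(VI)"
#' parse_species_token("glucose")$kind          # "molecule"
#' @seealso [expand_joint_tokens()]
#' @export
parse_species_token <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    cqd_error("cqd_parse_error", "species token must be a single string")
  }
  raw <- trimws(token)
  if (!nzchar(raw)) {
    cqd_error("cqd_parse_error", "empty species token")
  }

  # normalize extraction artefacts: unicode minus/dashes, subscript markers,
  # stray caret pairs, radical dots
  t <- raw
  t <- gsub("−|–|—", "-", t)
  t <- gsub("_", "", t)
  t <- gsub("\\^\\^", "^", t)
  radical_dot <- grepl("[∙•·]|\\^\\.|\\.\\-$|\\.\\+$", t)
  t <- gsub("[∙•·]", "", t)
  t <- sub("\\^(.*)\\^", "^\\1", t)      # "^3+^" -> "^3+"
  t <- gsub("\\^\\.", "^", t)            # "O2^.-" -> "O2^-"
  t <- trimws(gsub("\\s+\\^", "^", t))   # "Sc ^3+" -> "Sc^3+"

  n_plus <- lengths(regmatches(t, gregexpr("\\+", t)))
  n_minus_mark <- lengths(regmatches(t, gregexpr("\\^[0-9]*-|-$", t)))
  if (n_plus > 0L && n_minus_mark > 0L) {
    cqd_error("cqd_parse_error",
              sprintf("contradictory charge markers in token '%s'", raw))
  }

  core <- t
  charge <- 0L
  if (grepl("\\^[0-9]*[+-]$", t)) {            # Fe^3+, K^+, SO4^2-
    m <- regmatches(t, regexec("^(.*?)\\^([0-9]*)([+-])$", t))[[1]]
    core <- m[2]
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    charge <- if (m[4] == "+") n else -n
  } else if (grepl("\\^[+-][0-9]+$", t)) {     # Fe^+2
    m <- regmatches(t, regexec("^(.*?)\\^([+-])([0-9]+)$", t))[[1]]
    core <- m[2]
    charge <- if (m[3] == "+") as.integer(m[4]) else -as.integer(m[4])
  } else if (grepl("[A-Za-z0-9)][+-]$", t) && !grepl("\\s", t)) {  # Mn+, Br-
    m <- regmatches(t, regexec("^(.*?)([+-])$", t))[[1]]
    core <- m[2]
    charge <- if (m[3] == "+") 1L else -1L
  }
  if (!nzchar(core)) {
    cqd_error("cqd_parse_error",
              sprintf("no species core in token '%s'", raw))
  }

  is_element <- core %in% ELEMENT_SYMBOLS
  is_formula <- grepl("^[A-Za-z0-9()]+$", core) && grepl("[A-Z]", core)

  if (is_element) {
    element <- core
    oxidation_state <- if (charge != 0L) charge else NA_integer_
    if (charge > 0L) {
      kind <- "cation"
      canonical <- sprintf("%s(%s)", element, roman_numeral(charge))
    } else if (charge < 0L) {
      kind <- "anion"
      canonical <- sprintf("%s(-%s)", element, roman_numeral(-charge))
    } else {
      kind <- if (radical_dot) "radical" else "molecule"
      canonical <- element
    }
  } else if (is_formula) {
    key <- toupper(core)
    if (charge < 0L && key %in% names(OXOANION_STATES)) {
      ox <- OXOANION_STATES[[key]]
      element <- ox$element
      oxidation_state <- ox$state
      kind <- "anion"
      canonical <- sprintf("%s(%s)", element, roman_numeral(ox$state))
    } else {
      element <- ""
      oxidation_state <- NA_integer_
      if (charge > 0L) {
        kind <- "cation"
        canonical <- sprintf("%s(%d+)", core, charge)
      } else if (charge < 0L) {
        kind <- "anion"
        canonical <- sprintf("%s(%d-)", core, -charge)
      } else {
        kind <- if (radical_dot) "radical" else "molecule"
        canonical <- tolower(core)
      }
    }
  } else {
    # free-text organic name ("citric acid", "unobtainium extract")
    element <- ""
    oxidation_state <- NA_integer_
    kind <- if (radical_dot) "radical" else "molecule"
    charge <- 0L
    canonical <- tolower(core)
  }

  structure(
    list(
      raw_token = raw,
      element = element,
      charge = as.integer(charge),
      oxidation_state = oxidation_state,
      kind = kind,
      canonical_id = canonical
    ),
    class = "chem_species"
  )
}

#' Expand a joint (slash-separated) species token
#'
#' Selectivity tables occasionally list joint redox challenges such as
#' `"Fe^2+/Fe^3+"`; each alternative is an explicit challenge and expands to
#' its own species.
#'
#' @param token Character scalar, possibly containing `/`-separated
#'   alternatives.
#' @return A list of `chem_species`, one per alternative (a singleton list for
#'   plain tokens).
#' @export
expand_joint_tokens <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    cqd_error("cqd_parse_error", "species token must be a single string")
  }
  if (grepl("^\\s*/|/\\s*$|//", token)) {
    cqd_error("cqd_parse_error",
              sprintf("malformed joint token '%s'", token))
  }
  parts <- strsplit(token, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(trimws(parts)))) {
    cqd_error("cqd_parse_error",
              sprintf("malformed joint token '%s'", token))
  }
  lapply(parts, parse_species_token)
}

#' Render a species in normalized notation
#'
#' Inverse of [parse_species_token()] up to notation: monatomic ions render as
#' `"Fe^3+"`/`"Cl^-"`, polyatomic ions as `"SO4^2-"`, molecules as their raw
#' name.  `parse_species_token(render_species(x))` equals `x` up to
#' `raw_token`.
#'
#' @param sp A `chem_species`.
#' @return Character scalar.
#' @export
render_species <- function(sp) {
  stopifnot(inherits(sp, "chem_species"))
  if (sp$kind %in% c("molecule", "radical") && sp$charge == 0L) {
    return(sp$raw_token)
  }
  core <- if (nzchar(sp$element) && is.na(sp$oxidation_state)) {
    sp$element
  } else if (nzchar(sp$element) && !is.na(sp$oxidation_state) &&
             sp$oxidation_state == sp$charge) {
    sp$element
  } else {
    # polyatomic: recover the formula from the raw token
    t <- gsub("−|–|—", "-", gsub("_", "", sp$raw_token))
    t <- gsub("[∙•·]|\\.", "", t)
    sub("\\^.*$", "", sub("([+-])$", "", t))
  }
  n <- abs(sp$charge)
  sign <- if (sp$charge > 0L) "+" else "-"
  if (n == 1L) paste0(core, "^", sign) else paste0(core, "^", n, sign)
}

#' @export
print.chem_species <- function(x, ...) {
  cat(sprintf("<chem_species> %s  [%s, charge %+d] raw: \"%s\"\n",
              x$canonical_id, x$kind, x$charge, x$raw_token))
  invisible(x)
}

#' @export
format.chem_species <- function(x, ...) x$canonical_id

species_equal <- function(a, b) {
  identical(a$canonical_id, b$canonical_id) &&
    identical(a$kind, b$kind) && identical(a$charge, b$charge)
}
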