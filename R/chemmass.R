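# Elemental/formula arithmetic and the diagnostic-fragment registry.
# All ion m/z values are electron-inclusive: the printed masses of the
# class-diagnostic fragments (74.0248, 96.9601, 193.0354, ...) are only
# reproduced at 4 d.p. when the electron mass is added to the anion.

# IUPAC monoisotopic masses of the most abundant isotope, >= 6 decimals.
# "D" is the deuterium pseudo-element used for labelled internal standards.
.ELEMENT_MASS <- c(
  C = 12.000000000,
  H = 1.007825032,
  D = 2.014101778,
  N = 14.003074005,
  O = 15.994914620,
  P = 30.973761998,
  S = 31.972071174
)

.ELECTRON_MASS <- 0.000548580
.C13_C12_DELTA <- 1.0033548

#' Parse a molecular formula
#'
#' Parses a Hill-style composition string (e.g. `"C24H40O5"`) into a named
#' integer vector of element counts. Deuterium is written `D`. Only elements
#' with a defined monoisotopic mass (C, H, D, N, O, P, S) are accepted.
#'
#' @param text A formula string.
#' @return A named integer vector of class `chem_formula` (element counts).
#' @examples
#' parse_formula("C24H40O5")   # cholic acid
#' parse_formula("C2H4NO2")    # deprotonated glycine composition
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single formula string")
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) return(structure(integer(0), class = "chem_formula"))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(tokens)) != nchar(s))
    stop("cannot parse formula: '", text, "'")
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  bad <- setdiff(unique(syms), names(.ELEMENT_MASS))
  if (length(bad))
    stop("unknown element symbol: ", paste(bad, collapse = ", "))
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[out > 0L]
  structure(out[order(match(names(out), names(.ELEMENT_MASS)))],
            class = "chem_formula")
}

#' Render a formula in canonical Hill-style order
#'
#' Order is C, H (with D immediately after H), then remaining elements
#' alphabetically. `parse_formula(format_formula(f))` is the identity.
#'
#' @param f A `chem_formula` (or named count vector).
#' @return A single formula string.
#' @export
format_formula <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return("")
  nm <- names(f)
  ord <- c("C", "H", "D", sort(setdiff(nm, c("C", "H", "D"))))
  f <- f[ord[ord %in% nm]]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

.as_formula <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (is.null(names(f)) && length(f))
    stop("formula must be a named count vector or a string")
  bad <- setdiff(names(f), names(.ELEMENT_MASS))
  if (length(bad))
    stop("unknown element symbol: ", paste(bad, collapse = ", "))
  if (any(f < 0)) stop("element counts must be non-negative")
  v <- as.integer(f[f > 0])
  names(v) <- names(f)[f > 0]
  structure(v, class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a neutral composition
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#'
#' @param f Formula (string or `chem_formula`).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C24H40O5")  # 408.28757
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  sum(.ELEMENT_MASS[names(f)] * as.numeric(f))
}

#' Ion m/z for negative-mode species
#'
#' Computes the m/z of a singly charged (-1) ion from a neutral composition
#' and an adduct kind. The electron mass is always included.
#'
#' * `"[M-H]-"`  : M - m(H) + m(e)
#' * `"[M+CH3COO]-"` : M + m(C2H3O2) + m(e)  (acetate adduct, choline lipids)
#' * `"anion"`   : the composition already is the charged fragment;
#'                 m/z = m(composition) + m(e)
#'
#' @param neutral Formula of the neutral molecule (or of the anion itself for
#'   `adduct = "anion"`).
#' @param adduct One of `"[M-H]-"`, `"[M+CH3COO]-"`, `"anion"`.
#' @return A list of class `ion_species` with `neutral_formula`, `adduct`,
#'   `charge` (-1) and `mz`.
#' @examples
#' ion_mz("C2H4NO2", "anion")$mz       # 74.0248, glycine fragment
#' ion_mz("C24H40O5", "[M-H]-")$mz     # 407.2803, cholic acid
#' @export
ion_mz <- function(neutral, adduct = c("[M-H]-", "[M+CH3COO]-", "anion")) {
  adduct <- match.arg(adduct)
  f <- .as_formula(neutral)
  m <- monoisotopic_mass(f)
  mz <- switch(adduct,
    "[M-H]-"      = m - .ELEMENT_MASS[["H"]] + .ELECTRON_MASS,
    "[M+CH3COO]-" = m + monoisotopic_mass("C2H3O2") + .ELECTRON_MASS,
    "anion"       = m + .ELECTRON_MASS
  )
  if (mz <= 0) stop("computed m/z is not positive")
  structure(list(neutral_formula = f, adduct = adduct, charge = -1L, mz = mz),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion> %s %s  m/z %.4f (z = %d)\n",
              format_formula(x$neutral_formula), x$adduct, x$mz, x$charge))
  invisible(x)
}

#' Symmetric ppm mass-tolerance window
#'
#' @param mz Centre m/z (Da), > 0.
#' @param tol Tolerance in ppm, > 0.
#' @return Numeric `c(lo, hi)` with `lo = mz*(1 - tol*1e-6)`.
#' @export
ppm_window <- function(mz, tol = 5) {
  if (any(mz <= 0) || any(tol <= 0)) stop("mz and tol must be positive")
  c(mz * (1 - tol * 1e-6), mz * (1 + tol * 1e-6))
}

#' M+1 isotope m/z
#'
#' The first carbon-isotope satellite of a singly charged ion:
#' `mz + 1.0033548` (the 13C-12C mass difference).
#'
#' @param mz Monoisotopic m/z, > 0.
#' @return m/z of the M+1 signal.
#' @export
isotope_m1 <- function(mz) {
  if (any(mz <= 0)) stop("mz must be positive")
  mz + .C13_C12_DELTA
}

# Cached registry read from the shipped TSV resource.
.registry_env <- new.env(parent = emptyenv())

.load_registry <- function() {
  if (!is.null(.registry_env$tab)) return(.registry_env$tab)
  path <- system.file("extdata", "fragment_registry.tsv", package = "aifquant")
  if (path == "") path <- file.path("inst", "extdata", "fragment_registry.tsv")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .registry_env$tab <- tab
  tab
}

#' Diagnostic-fragment registry
#'
#' Returns the class-diagnostic fragments used for AIF co-elution
#' confirmation. Conjugated bile acids and LPL head groups come from the
#' shipped TSV resource; fatty-acyl carboxylate fragments
#' (`"fatty-acyl(C:db)"`, CnH(2n-2db-1)O2-) are computed on demand.
#'
#' Known class tags: `glycine-conjugate`, `taurine-conjugate`, `sulfate`,
#' `glucuronide`, `LPL-headgroup-PC`, `-PE`, `-PI`, `-PS`, `-PG`, and
#' `fatty-acyl(n:db)`.
#'
#' @param class_tag Compound-class tag.
#' @return A data frame with columns `name`, `composition`, `kind`
#'   (`"anion"` or `"neutral-loss"`), `mz` (Da; `NA` for neutral losses,
#'   whose `loss_mass` column carries the neutral mass) and `class_tag`.
#' @examples
#' fragment_registry("taurine-conjugate")
#' fragment_registry("fatty-acyl(16:0)")
#' @export
fragment_registry <- function(class_tag) {
  acyl <- regmatches(class_tag,
                     regexec("^fatty-acyl\\((\\d+):(\\d+)\\)$", class_tag))[[1]]
  if (length(acyl) == 3L) {
    n <- as.integer(acyl[2]); db <- as.integer(acyl[3])
    comp <- sprintf("C%dH%dO2", n, 2L * n - 2L * db - 1L)
    return(data.frame(
      name = sprintf("FA %d:%d carboxylate", n, db),
      composition = comp, kind = "anion",
      mz = ion_mz(comp, "anion")$mz, loss_mass = NA_real_,
      class_tag = class_tag, stringsAsFactors = FALSE))
  }
  tab <- .load_registry()
  hit <- tab[tab$class_tag == class_tag, , drop = FALSE]
  if (!nrow(hit)) stop("unknown compound class: '", class_tag, "'")
  hit$loss_mass <- ifelse(hit$kind == "neutral-loss",
                          vapply(hit$composition, monoisotopic_mass, 0),
                          NA_real_)
  rownames(hit) <- NULL
  hit[, c("name", "composition", "kind", "mz", "loss_mass", "class_tag")]
}
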