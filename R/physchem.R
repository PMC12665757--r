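# ProtParam-compatible physicochemical profiling.
#
# All properties are sequence-only estimates: molecular weight from average
# residue masses, pI by charge-balance bisection over the Bjellqvist pKa set,
# instability by the Guruprasad dipeptide-weight method, GRAVY/logP from the
# Kyte-Doolittle scale, and PSA as 50 A^2 per polar residue. Non-standard
# residues inherit their base residue's values unless an override row matches.

as_tokens <- function(x) {
  if (inherits(x, "pep_tokens")) return(x)
  if (is.character(x) && length(x) == 1L) return(pep_tokenize(x))
  if (is.character(x)) return(structure(x, class = "pep_tokens"))
  stop("expected a sequence string or a pep_tokens vector", call. = FALSE)
}

#' NSAA property overrides
#'
#' Reads a table assigning explicit property contributions to non-standard
#' residue tokens. Columns: `token_pattern` (regular expression matched
#' against the full bracket token), `delta_mass_Da` (added to the base residue
#' mass), `kd_value` (replaces the base Kyte-Doolittle value; blank keeps it),
#' `charge` (replaces the formal side-chain charge) and `polar_flag`
#' (overrides polar-set membership). The packaged default covers common
#' gamma-glutamate-linked acyl chains; its mass increments are synthetic
#' estimates from the side-chain composition, not measured reference values.
#'
#' @param path CSV path; `NULL` loads the packaged default table.
#' @return A tibble.
#' @export
nsaa_overrides <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nsaa_overrides_synthetic.csv",
                        package = "triagonist")
  }
  readr::read_csv(path, col_types = readr::cols(
    token_pattern = readr::col_character(),
    delta_mass_Da = readr::col_double(),
    kd_value = readr::col_double(),
    charge = readr::col_double(),
    polar_flag = readr::col_integer()
  ))
}

# Per-token property lookup honouring overrides.
# Returns a list of parallel vectors: base, mass, kd, charge, polar.
token_props <- function(tokens, overrides = NULL) {
  tokens <- as_tokens(tokens)
  base <- token_base(tokens)
  if (anyNA(base)) {
    stop("token without a valid base residue: ",
         paste(unclass(tokens)[is.na(base)], collapse = ", "), call. = FALSE)
  }
  mass <- unname(AA_MASS[base]) - MASS_WATER
  kd <- unname(AA_KD[base])
  charge <- unname(AA_CHARGE_PHYS[base])
  polar <- base %in% AA_POLAR
  is_nsaa <- grepl("^\\[", unclass(tokens))
  if (any(is_nsaa) && !is.null(overrides) && nrow(overrides) > 0) {
    for (i in which(is_nsaa)) {
      hit <- which(vapply(overrides$token_pattern,
                          function(p) grepl(p, unclass(tokens)[i]), logical(1)))
      if (length(hit) > 0) {
        row <- overrides[hit[1L], ]
        if (!is.na(row$delta_mass_Da)) mass[i] <- mass[i] + row$delta_mass_Da
        if (!is.na(row$kd_value)) kd[i] <- row$kd_value
        if (!is.na(row$charge)) charge[i] <- row$charge
        if (!is.na(row$polar_flag)) polar[i] <- row$polar_flag > 0
      }
    }
  }
  list(base = base, mass = mass, kd = kd, charge = charge, polar = polar)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle value over all residues. NSAA tokens use their base
#' residue's value unless overridden.
#'
#' @param x Sequence string or `pep_tokens`.
#' @param overrides Optional NSAA override tibble (see [nsaa_overrides()]).
#' @return Numeric scalar in \[-4.5, 4.5\].
#' @export
pep_gravy <- function(x, overrides = NULL) {
  p <- token_props(x, overrides)
  mean(p$kd)
}

#' Estimated logP
#'
#' Length-normalized Kyte-Doolittle lipophilicity; under the default
#' parameterization this equals the GRAVY score.
#'
#' @inheritParams pep_gravy
#' @export
pep_logp <- function(x, overrides = NULL) {
  pep_gravy(x, overrides)
}

#' Estimated polar surface area
#'
#' Counts residues whose base letter is in the polar set
#' \{S, T, N, Q, D, E, H, K, R\} and applies 50 angstrom^2 per polar residue.
#'
#' @inheritParams pep_gravy
#' @return Non-negative multiple of 50 (angstrom^2).
#' @export
pep_psa <- function(x, overrides = NULL) {
  p <- token_props(x, overrides)
  50 * sum(p$polar)
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da) for an unmodified
#' linear peptide.
#'
#' @inheritParams pep_gravy
#' @return Mass in Da.
#' @export
pep_mw <- function(x, overrides = NULL) {
  p <- token_props(x, overrides)
  sum(p$mass) + MASS_WATER
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch partial charges over the N-terminus, C-terminus and
#' the ionizable side chains (D, E, C, Y, H, K, R) with the Bjellqvist pKa
#' set. NSAA tokens contribute their base residue's side chain.
#'
#' @inheritParams pep_gravy
#' @param pH pH at which to evaluate the net charge.
#' @export
pep_charge <- function(x, pH = 7.0, overrides = NULL) {
  p <- token_props(x, overrides)
  counts <- table(factor(p$base, levels = AA_STANDARD))
  first <- p$base[1]
  last <- p$base[length(p$base)]
  nt_pka <- if (first %in% names(PKA_NTERM_BY_RESIDUE)) {
    PKA_NTERM_BY_RESIDUE[[first]]
  } else PKA_POSITIVE[["Nterm"]]
  ct_pka <- if (last %in% names(PKA_CTERM_BY_RESIDUE)) {
    PKA_CTERM_BY_RESIDUE[[last]]
  } else PKA_NEGATIVE[["Cterm"]]
  pos <- 1 / (10^(pH - nt_pka) + 1)
  for (aa in c("K", "R", "H")) {
    pos <- pos + counts[[aa]] / (10^(pH - PKA_POSITIVE[[aa]]) + 1)
  }
  neg <- 1 / (10^(ct_pka - pH) + 1)
  for (aa in c("D", "E", "C", "Y")) {
    neg <- neg + counts[[aa]] / (10^(PKA_NEGATIVE[[aa]] - pH) + 1)
  }
  unname(pos - neg)
}

#' Isoelectric point
#'
#' pH at which the net charge of [pep_charge()] vanishes, located by bisection.
#' The default start, bracket and termination mirror the ProtParam convention
#' (start 7.775, bracket \[4.05, 12\], stop when the bracket is narrower than
#' `tol`), so values agree with ProtParam output to the fifth decimal.
#'
#' @inheritParams pep_gravy
#' @param lo,hi,start Bisection bracket and starting pH.
#' @param tol Bracket width at which bisection stops.
#' @return pH units.
#' @export
pep_pi <- function(x, overrides = NULL, lo = 4.05, hi = 12.0, start = 7.775,
                   tol = 1e-4) {
  tokens <- as_tokens(x)
  pH <- start
  repeat {
    if (hi - lo <= tol) return(pH)
    if (pep_charge(tokens, pH, overrides) > 0) lo <- pH else hi <- pH
    pH <- (lo + hi) / 2
  }
}

#' Instability index
#'
#' Guruprasad dipeptide-weight method: `(10 / L) * sum` of DIWV weights over
#' consecutive residue pairs (base residues for NSAA tokens). Values above 40
#' conventionally predict in-vitro instability.
#'
#' @inheritParams pep_gravy
#' @export
pep_instability <- function(x, overrides = NULL) {
  p <- token_props(x, overrides)
  L <- length(p$base)
  if (L < 2) stop("instability index requires at least 2 residues", call. = FALSE)
  idx <- cbind(
    match(p$base[-L], AA_STANDARD),
    match(p$base[-1], AA_STANDARD)
  )
  (10 / L) * sum(DIWV[idx])
}

#' Full physicochemical profile
#'
#' Computes the property panel used to characterize designed candidates:
#' molecular weight, isoelectric point, instability index, GRAVY, estimated
#' logP, estimated PSA, plus net charge at pH 7 and token length.
#'
#' @param x A data frame with a `sequence` column (columns are appended), or a
#'   character vector of sequences, or a single `pep_tokens`.
#' @param overrides Optional NSAA override tibble.
#' @return A tibble; for data-frame input, the input with profile columns
#'   appended.
#' @examples
#' pep_properties("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
#' @export
pep_properties <- function(x, overrides = NULL) {
  if (is.data.frame(x)) {
    prof <- pep_properties(x$sequence, overrides)
    return(dplyr::bind_cols(x, prof[setdiff(names(prof), names(x))]))
  }
  seqs <- if (inherits(x, "pep_tokens")) list(x) else tokenize_all(x)
  rows <- purrr::map(seqs, function(tok) {
    tibble::tibble(
      length = length(tok),
      mol_weight = pep_mw(tok, overrides),
      isoelectric = pep_pi(tok, overrides),
      instability_index = pep_instability(tok, overrides),
      gravy = pep_gravy(tok, overrides),
      est_logP = pep_logp(tok, overrides),
      est_psa = pep_psa(tok, overrides),
      net_charge_ph7 = pep_charge(tok, 7.0, overrides)
    )
  })
  dplyr::bind_rows(rows)
}
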