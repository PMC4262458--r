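#' CYP nomenclature identity thresholds
#'
#' The standard cutoffs for assigning a query to nomenclature tiers by
#' amino-acid identity to a named reference: >= 97\% allelic variant,
#' >= 55\% same subfamily, >= 40\% same family, below 40\% unrelated
#' (discarded as contamination / non-plant).  Boundary values classify
#' to the higher rank (>= semantics).
#'
#' Identity is only interpreted when the underlying alignment covers at
#' least `min_aligned_cols` columns; shorter alignments (chance islands
#' in unrelated sequence) are discarded as unrelated.
#'
#' @param variant_min,subfamily_min,family_min identity cutoffs.
#' @param min_aligned_cols minimum aligned columns for a rankable
#'   identity.
#' @return list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(variant_min = 0.97,
                                      subfamily_min = 0.55,
                                      family_min = 0.40,
                                      min_aligned_cols = 50L) {
  if (!(family_min < subfamily_min && subfamily_min < variant_min))
    stop("thresholds must satisfy family_min < subfamily_min < variant_min")
  structure(list(variant_min = variant_min, subfamily_min = subfamily_min,
                 family_min = family_min,
                 min_aligned_cols = as.integer(min_aligned_cols)),
            class = "classification_thresholds")
}

#' Nearest reference in a panel
#'
#' Argmax of [pairwise_identity()] over the panel.  References whose
#' alignment to the query spans fewer than `min_cols` columns are not
#' considered (their identity is a chance island, not a homology
#' signal); if no reference aligns over `min_cols` columns the best
#' overall is returned with `eligible = FALSE`.  Ties are broken by the
#' longer reference, then by lexicographic name; tie events are
#' reported via `message()`.
#'
#' @param query protein string.
#' @param panel a reference panel (data.frame with `name`, `protein`).
#' @param min_cols minimum aligned columns for a reference to count.
#' @return list with `name`, `identity`, `tie`, `columns`, `eligible`.
#' @export
nearest_reference <- function(query, panel, min_cols = 0) {
  stopifnot(nrow(panel) > 0)
  alns <- lapply(panel$protein, function(p) align_glocal(query, p))
  ids <- vapply(alns, function(a)
    if (a$columns > 0) a$matches / a$columns else 0, numeric(1))
  cols <- vapply(alns, function(a) a$columns, numeric(1))
  eligible <- cols >= min_cols
  pool <- if (any(eligible)) which(eligible) else seq_along(ids)
  best <- max(ids[pool])
  cand <- pool[ids[pool] == best]
  tie <- length(cand) > 1
  if (tie) {
    lens <- nchar(panel$protein[cand])
    cand <- cand[lens == max(lens)]
    cand <- cand[order(panel$name[cand])]
    message("nearest_reference tie at identity ",
            format(best, digits = 4), ": ",
            paste(panel$name[pool[ids[pool] == best]], collapse = ", "),
            " -> ", panel$name[cand[1]])
  }
  list(name = panel$name[cand[1]], identity = best, tie = tie,
       columns = alns[[cand[1]]]$columns, eligible = any(eligible))
}

#' Nomenclature rank from an identity value
#'
#' @param identity identity fraction in \[0, 1\].
#' @param th a [classification_thresholds()].
#' @return one of `"allelic_variant"`, `"same_subfamily"`,
#'   `"same_family"`, `"unrelated"`.
#' @examples
#' assign_rank(0.98)  # allelic_variant
#' assign_rank(0.60)  # same_subfamily
#' assign_rank(0.39)  # unrelated
#' @export
assign_rank <- function(identity, th = classification_thresholds()) {
  stopifnot(all(identity >= 0 & identity <= 1))
  ifelse(identity >= th$variant_min, "allelic_variant",
    ifelse(identity >= th$subfamily_min, "same_subfamily",
      ifelse(identity >= th$family_min, "same_family", "unrelated")))
}

#' Create a naming registry from a reference panel
#'
#' The registry tracks every name in use (panel plus assignments) so new
#' member numbers and subfamily letters are allocated deterministically
#' and collisions fail loudly.
#'
#' @param panel reference panel (data.frame with `name`, `family`,
#'   `subfamily`, `clan`).
#' @return environment of class `name_registry`.
#' @export
name_registry <- function(panel) {
  reg <- new.env(parent = emptyenv())
  reg$names <- panel$name
  reg$subfamilies <- unique(panel[, c("family", "subfamily")])
  reg$clan_map <- unique(panel[, c("family", "clan")])
  class(reg) <- "name_registry"
  reg
}

# next free member number within a subfamily label, e.g. CYP901A -> 3
next_member_number <- function(reg, subfamily) {
  pat <- paste0("^", subfamily, "([0-9]+)$")
  hits <- grep(pat, reg$names, value = TRUE)
  used <- as.integer(sub(pat, "\\1", hits))
  n <- 1L
  while (n %in% used) n <- n + 1L
  n
}

# subfamily letter sequence A..Z, AA, AB, ...
letter_seq <- function(k) {
  out <- character(k); i <- 0L
  while (i < k) {
    i <- i + 1L
    n <- i; s <- ""
    while (n > 0) { r <- (n - 1) %% 26; s <- paste0(LETTERS[r + 1], s)
                    n <- (n - 1) %/% 26 }
    out[i] <- s
  }
  out
}

next_subfamily_letter <- function(reg, family) {
  used <- sub(paste0("^", family), "",
              reg$subfamilies$subfamily[reg$subfamilies$family == family])
  for (l in letter_seq(200)) if (!l %in% used) return(l)
  stop("subfamily letters exhausted for ", family)
}

register_name <- function(reg, name) {
  if (name %in% reg$names)
    stop("registry collision: ", name, " already assigned")
  reg$names <- c(reg$names, name)
  invisible(name)
}

#' Assign a provisional CYP name to a query protein
#'
#' Applies the nomenclature rules against the registry: an allelic
#' variant inherits the reference name (recorded as a variant of it,
#' without claiming a new registry entry); a same-subfamily hit receives
#' the reference subfamily with the next free member number; a
#' same-family hit opens the first unused subfamily letter.  Partial
#' sequences are classified at their best supported rank with a
#' provisional flag and never consume a new subfamily letter.
#'
#' @param gene_id query identifier.
#' @param query protein string.
#' @param panel reference panel.
#' @param registry a [name_registry()] (updated in place).
#' @param th a [classification_thresholds()].
#' @param status curation status (`"full"`, `"partial"`, `"flagged"`).
#' @return one-row data.frame (`ClassifiedGene`): `gene_id`,
#'   `assigned_name`, `family`, `subfamily`, `clan`, `cyp_type`,
#'   `status`, `nearest_ref`, `identity`, `rank`, `provisional`.
#' @export
assign_name <- function(gene_id, query, panel, registry,
                        th = classification_thresholds(),
                        status = "full") {
  nr <- nearest_reference(query, panel, min_cols = th$min_aligned_cols)
  rank <- assign_rank(nr$identity, th)
  if (!nr$eligible) rank <- "unrelated"
  ref <- panel[panel$name == nr$name, ]
  clan <- registry$clan_map$clan[registry$clan_map$family == ref$family][1]
  partial <- status != "full"
  if (rank == "unrelated")
    return(data.frame(gene_id = gene_id, assigned_name = NA_character_,
                      family = NA_character_, subfamily = NA_character_,
                      clan = NA_character_, cyp_type = NA_character_,
                      status = status, nearest_ref = nr$name,
                      identity = nr$identity, rank = rank,
                      provisional = FALSE, stringsAsFactors = FALSE))
  if (rank == "allelic_variant") {
    nm <- nr$name                       # inherited, not re-registered
    fam <- ref$family; sub <- ref$subfamily
  } else if (rank == "same_subfamily") {
    sub <- ref$subfamily; fam <- ref$family
    nm <- paste0(sub, next_member_number(registry, sub))
    register_name(registry, nm)
  } else {                              # same_family
    fam <- ref$family
    if (partial) {
      sub <- NA_character_              # partials never open a subfamily
      nm <- paste0(fam, ".", gene_id)
    } else {
      letter <- next_subfamily_letter(registry, fam)
      sub <- paste0(fam, letter)
      registry$subfamilies <- rbind(registry$subfamilies,
                                    data.frame(family = fam,
                                               subfamily = sub))
      nm <- paste0(sub, 1L)
      register_name(registry, nm)
    }
  }
  data.frame(gene_id = gene_id, assigned_name = nm, family = fam,
             subfamily = sub, clan = clan,
             cyp_type = if (identical(clan, "71")) "A" else "non-A",
             status = status, nearest_ref = nr$name,
             identity = nr$identity, rank = rank,
             provisional = partial, stringsAsFactors = FALSE)
}

#' Classify a set of curated proteins against a reference panel
#'
#' Runs [assign_name()] over the proteins in order, maintaining one
#' registry.  Queries below the family cutoff are retained in the output
#' with rank `"unrelated"` (discard reason: contamination / non-plant).
#'
#' @param proteins named character vector of protein sequences.
#' @param panel reference panel.
#' @param status named character vector of curation statuses (defaults
#'   to `"full"` for all).
#' @param th a [classification_thresholds()].
#' @return data.frame of classified genes, one row per query.
#' @export
classify_proteins <- function(proteins, panel, status = NULL,
                              th = classification_thresholds()) {
  if (is.null(status))
    status <- setNames(rep("full", length(proteins)), names(proteins))
  reg <- name_registry(panel)
  rows <- lapply(names(proteins), function(id)
    assign_name(id, proteins[[id]], panel, reg, th,
                status = status[[id]]))
  out <- do.call(rbind, rows)
  attr(out, "registry") <- reg
  out
}
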