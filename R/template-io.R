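SUB_PATHWAYS <- c("calvin_cycle", "sucrose_synthesis", "starch_synthesis", "other")
EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

split_multi <- function(x) {
  if (!length(x)) return(list())
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

join_multi <- function(x) vapply(x, paste, character(1), collapse = ";")

check_ec <- function(ec, where) {
  bad <- ec[!grepl(EC_PATTERN, ec)]
  if (length(bad)) {
    stop("malformed EC number(s) in ", where, ": ",
         paste(unique(bad), collapse = ", "),
         " (expected four dot-separated fields)", call. = FALSE)
  }
  invisible(ec)
}

#' Construct a pathway template
#'
#' The template describes the reference pathway to be reconstructed: an
#' ordered list of reactions keyed by EC number, each labelled with one of
#' the sub-pathways (`calvin_cycle`, `sucrose_synthesis`,
#' `starch_synthesis`, `other`), plus the template genes of each species
#' with their function labels, EC numbers and annotation clarity
#' (`clear`/`unclear`). Template genes whose EC numbers fall outside the
#' union of reaction ECs are flagged `auxiliary`.
#'
#' @param name template name.
#' @param reactions data frame with columns `reaction_id`, `ec_numbers`
#'   (`;`-separated), `substrates` (`;`), `products` (`;`), `sub_pathway`.
#' @param genes data frame with columns `species`, `gene_id`,
#'   `function_label`, `ec_numbers` (`;`-separated, may be empty),
#'   `clarity`.
#' @return An object of class `pathway_template`.
#' @export
pathway_template <- function(name, reactions, genes) {
  need_r <- c("reaction_id", "ec_numbers", "substrates", "products", "sub_pathway")
  need_g <- c("species", "gene_id", "function_label", "ec_numbers", "clarity")
  if (!all(need_r %in% names(reactions))) {
    stop("reactions must have columns: ", paste(need_r, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_g %in% names(genes))) {
    stop("genes must have columns: ", paste(need_g, collapse = ", "),
         call. = FALSE)
  }
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)[need_r]
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)[need_g]
  if (anyDuplicated(reactions$reaction_id)) {
    stop("duplicate reaction_id(s): ",
         paste(unique(reactions$reaction_id[duplicated(reactions$reaction_id)]),
               collapse = ", "), call. = FALSE)
  }
  rec <- split_multi(reactions$ec_numbers)
  if (any(lengths(rec) == 0L)) {
    stop("reaction(s) without an EC number: ",
         paste(reactions$reaction_id[lengths(rec) == 0L], collapse = ", "),
         call. = FALSE)
  }
  check_ec(unlist(rec), "reactions")
  bad_sp <- setdiff(unique(reactions$sub_pathway), SUB_PATHWAYS)
  if (length(bad_sp)) {
    stop("unknown sub_pathway label(s): ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$clarity %in% c("clear", "unclear"))) {
    stop("gene clarity must be 'clear' or 'unclear'", call. = FALSE)
  }
  gec <- split_multi(genes$ec_numbers)
  check_ec(unlist(gec), "template genes")
  reaction_ecs <- unique(unlist(rec))
  genes$auxiliary <- vapply(gec, function(e) length(e) > 0 &&
                              !any(e %in% reaction_ecs), logical(1))
  structure(list(name = as.character(name), reactions = reactions,
                 genes = genes),
            class = "pathway_template")
}

#' @export
print.pathway_template <- function(x, ...) {
  cat(sprintf("<pathway_template> '%s': %d reaction(s), %d template gene(s) from %d species\n",
              x$name, nrow(x$reactions), nrow(x$genes),
              length(unique(x$genes$species))))
  tab <- table(factor(x$reactions$sub_pathway, levels = SUB_PATHWAYS))
  for (sp in names(tab)[tab > 0]) cat(sprintf("  %-18s %d\n", sp, tab[[sp]]))
  invisible(x)
}

template_reaction_ecs <- function(template) {
  setNames(split_multi(template$reactions$ec_numbers),
           template$reactions$reaction_id)
}

#' Read a pathway template from TSV or JSON
#'
#' The JSON layout mirrors [pathway_template()]: an object with `name`,
#' `reactions` and `genes` arrays. The TSV layout is a single table with a
#' leading `record` column: one `pathway` row carrying the name in `id`,
#' `reaction` rows (`id`, `ec_numbers`, `substrates`, `products`,
#' `sub_pathway`) and `gene` rows (`id` = gene id, `species`,
#' `function_label`, `ec_numbers`, `clarity`). Multi-valued fields are
#' `;`-separated. The format is chosen by file extension.
#'
#' @param path `.json` or `.tsv` file.
#' @return A [pathway_template()].
#' @export
read_pathway_template <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("name", "reactions", "genes") %in% names(obj))) {
      stop("template JSON must contain 'name', 'reactions' and 'genes'",
           call. = FALSE)
    }
    return(pathway_template(obj$name, obj$reactions, obj$genes))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("record", "id", "species", "function_label", "ec_numbers",
            "substrates", "products", "sub_pathway", "clarity")
  if (!all(need %in% names(tab))) {
    stop("template TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  name <- tab$id[tab$record == "pathway"]
  if (length(name) != 1L) stop("template TSV needs exactly one 'pathway' row",
                               call. = FALSE)
  r <- tab[tab$record == "reaction", , drop = FALSE]
  g <- tab[tab$record == "gene", , drop = FALSE]
  pathway_template(
    name,
    data.frame(reaction_id = r$id, ec_numbers = r$ec_numbers,
               substrates = r$substrates, products = r$products,
               sub_pathway = r$sub_pathway, stringsAsFactors = FALSE),
    data.frame(species = g$species, gene_id = g$id,
               function_label = g$function_label, ec_numbers = g$ec_numbers,
               clarity = g$clarity, stringsAsFactors = FALSE))
}

#' Write a pathway template to TSV or JSON
#'
#' Inverse of [read_pathway_template()]; the round trip is lossless for all
#' content fields.
#'
#' @param template a [pathway_template()].
#' @param path output path ending in `.json` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_pathway_template <- function(template, path) {
  stopifnot(inherits(template, "pathway_template"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    genes <- template$genes
    genes$auxiliary <- NULL
    jsonlite::write_json(list(name = template$name,
                              reactions = template$reactions,
                              genes = genes),
                         path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  r <- template$reactions
  g <- template$genes
  blank <- function(n) rep("", n)
  tab <- rbind(
    data.frame(record = "pathway", id = template$name, species = "",
               function_label = "", ec_numbers = "", substrates = "",
               products = "", sub_pathway = "", clarity = "",
               stringsAsFactors = FALSE),
    data.frame(record = "reaction", id = r$reaction_id, species = blank(nrow(r)),
               function_label = blank(nrow(r)), ec_numbers = r$ec_numbers,
               substrates = r$substrates, products = r$products,
               sub_pathway = r$sub_pathway, clarity = blank(nrow(r)),
               stringsAsFactors = FALSE),
    data.frame(record = "gene", id = g$gene_id, species = g$species,
               function_label = g$function_label, ec_numbers = g$ec_numbers,
               substrates = blank(nrow(g)), products = blank(nrow(g)),
               sub_pathway = blank(nrow(g)), clarity = g$clarity,
               stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
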