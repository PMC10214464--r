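#' Parse Greengenes-style taxonomy strings
#'
#' Extracts the genus from lineage annotations of the form
#' `"k__Bacteria; p__...; g__Nitrosomonas; s__"`.  Rank prefixes
#' (`k__` ... `s__`), surrounding whitespace and bracketed candidate-genus
#' markers (`[Genus]`) are stripped; an empty `g__` field yields an absent
#' genus (`NA`).  Malformed lineages are kept with genus absent and a
#' warning, never dropped.
#'
#' @param lines Character vector of lineage annotations, or a two-column
#'   `data.frame` (`otu_id`, `lineage`).
#' @param otu_ids OTU identifiers; defaults to names of `lines` or
#'   `OTU_1..n`.
#' @return `data.frame` with columns `otu_id`, `lineage`, `genus`
#'   (`NA_character_` when absent).
#' @examples
#' parseTaxonomy("k__Bacteria; p__; c__; o__; f__; g__Nitrosomonas; s__")
#' @export
parseTaxonomy <- function(lines, otu_ids = NULL) {
  if (is.data.frame(lines)) {
    otu_ids <- as.character(lines[[1]])
    lines <- as.character(lines[[2]])
  }
  if (is.null(otu_ids))
    otu_ids <- if (!is.null(names(lines))) names(lines)
               else paste0("OTU_", seq_along(lines))
  genus <- rep(NA_character_, length(lines))
  bad <- !grepl(";", lines) & !grepl("__", lines) & nzchar(trimws(lines))
  if (any(bad))
    warning(sum(bad), " lineage string(s) without rank structure; ",
            "genus left absent")
  hit <- regexpr("(^|[; ])g__[^;]*", lines)
  has <- hit > 0
  tok <- trimws(sub("^.*g__", "", regmatches(lines, hit)))
  tok <- gsub("^\\[|\\]$", "", tok)
  genus[has][nzchar(tok)] <- tok[nzchar(tok)]
  data.frame(otu_id = otu_ids, lineage = lines, genus = genus,
             stringsAsFactors = FALSE)
}

#' Read and validate a genus-to-guild map
#'
#' A guild map is a `data.frame` with columns `genus`, `guild`,
#' `exclude_flag` (logical; genera removed because a single metabolic
#' classification would be unrealistic -- multi-metabolism genera and
#' phototrophs) and `substrate_complexity`.  Assigned and excluded genera
#' are disjoint by construction (an excluded row's guild is ignored), and
#' every guild label must appear in the metabolism catalogue.
#'
#' The bundled fixture map (`inst/extdata/guild_map_fixture.csv`) covers
#' about 50 well-known genera curated from standard bacteriological
#' systematics; it is a small stand-in for a full genus classification,
#' sufficient for tests and examples.  Facultative aerobic fermenters
#' (e.g. *Escherichia*) carry the aerobic-heterotroph label.
#'
#' @param path CSV file with columns
#'   `genus,guild,exclude_flag,substrate_complexity`; the default reads
#'   the bundled fixture.
#' @param catalogue Metabolism catalogue whose names the guild labels must
#'   match.
#' @return Validated guild-map `data.frame` with attribute `excluded`
#'   (character vector of excluded genera).
#' @export
readGuildMap <- function(path = system.file("extdata",
                                            "guild_map_fixture.csv",
                                            package = "GuildEnergy"),
                         catalogue = defaultCatalogue()) {
  gm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "guild", "exclude_flag")
  if (!all(need %in% names(gm)))
    stop("guild map must have columns ", paste(need, collapse = ", "))
  gm$exclude_flag <- as.logical(gm$exclude_flag)
  if (anyDuplicated(gm$genus))
    stop("duplicated genera in guild map: ",
         paste(unique(gm$genus[duplicated(gm$genus)]), collapse = ", "))
  lab <- gm$guild[!gm$exclude_flag]
  unknown <- setdiff(lab, names(catalogue))
  if (length(unknown))
    stop("guild labels not in the metabolism catalogue: ",
         paste(unique(unknown), collapse = ", "))
  attr(gm, "excluded") <- gm$genus[gm$exclude_flag]
  gm
}

#' Assign OTUs to functional guilds
#'
#' Labels every OTU with exactly one guild, or marks it unassigned with a
#' reason: `genus_absent` (no genus in the lineage), `not_in_map`,
#' or `excluded` (multi-metabolism or phototrophic genera removed from the
#' analysis).  Genus matching is case-insensitive on trimmed tokens, so
#' trailing whitespace or case variation in annotations does not change
#' the assignment.  Unassignable taxa are counted, never fatal.
#'
#' @param records `data.frame` from [parseTaxonomy()].
#' @param map Guild map from [readGuildMap()].
#' @return A partition plan: `data.frame` with columns `otu_id`, `genus`,
#'   `guild` (`NA` when unassigned), `status`
#'   (`assigned`/`genus_absent`/`not_in_map`/`excluded`).
#' @export
assignGuilds <- function(records, map) {
  norm <- function(x) tolower(trimws(x))
  key <- norm(map$genus)
  idx <- match(norm(records$genus), key)
  status <- rep("assigned", nrow(records))
  guild <- rep(NA_character_, nrow(records))
  status[is.na(records$genus)] <- "genus_absent"
  status[!is.na(records$genus) & is.na(idx)] <- "not_in_map"
  hit <- which(status == "assigned")
  excl <- hit[map$exclude_flag[idx[hit]]]
  status[excl] <- "excluded"
  hit <- setdiff(hit, excl)
  guild[hit] <- map$guild[idx[hit]]
  if (length(hit) == 0)
    warning("no OTU matched the guild map; all taxa unassigned")
  # canonical genus spelling from the map for matched records
  genus <- records$genus
  matched <- !is.na(idx)
  genus[matched] <- map$genus[idx[matched]]
  data.frame(otu_id = records$otu_id, genus = genus, guild = guild,
             status = status, stringsAsFactors = FALSE)
}

#' Aggregate an OTU table into per-guild abundance vectors
#'
#' Applies a partition plan to a taxa-by-samples count table, summing
#' same-taxon OTUs within each guild, and returns a validated
#' [GuildedCounts-class].  Counts of unassigned OTUs accumulate in the
#' per-sample `unassigned` tally, so guild sums plus unassigned always
#' equal the sample total.
#'
#' @param otu_table Numeric matrix (or `data.frame`) of counts, rows =
#'   OTUs (rownames = OTU ids), columns = samples.
#' @param plan Partition plan from [assignGuilds()].
#' @param biomes Named character vector mapping sample name to biome
#'   label; unnamed scalar recycles to all samples.
#' @param unit `"genus"` (default: abundance vectors hold distinct genera)
#'   or `"otu"` (OTU-level resolution within guilds).
#' @return A [GuildedCounts-class].
#' @export
aggregateCounts <- function(otu_table, plan, biomes = "unknown",
                            unit = c("genus", "otu")) {
  unit <- match.arg(unit)
  m <- as.matrix(otu_table)
  if (is.null(rownames(m)))
    stop("otu_table must have OTU ids as rownames")
  if (!setequal(rownames(m), plan$otu_id))
    stop("OTU ids in table and plan disagree")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  plan <- plan[match(rownames(m), plan$otu_id), ]
  samples <- colnames(m)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  if (length(biomes) == 1 && is.null(names(biomes)))
    biomes <- stats::setNames(rep(biomes, length(samples)), samples)
  if (!all(samples %in% names(biomes)))
    stop("missing biome label for sample(s): ",
         paste(setdiff(samples, names(biomes)), collapse = ", "))

  assigned <- !is.na(plan$guild)
  taxon <- if (unit == "genus") plan$genus else plan$otu_id
  colnames(m) <- samples
  if (any(assigned)) {
    key <- paste(plan$guild[assigned], taxon[assigned], sep = "\r")
    agg <- rowsum(m[assigned, , drop = FALSE], group = key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    guildK <- vapply(parts, `[`, character(1), 1)
    taxonK <- vapply(parts, `[`, character(1), 2)
    nz <- which(agg > 0, arr.ind = TRUE)
    counts <- data.frame(
      sample = samples[nz[, 2]],
      biome = unname(biomes[samples[nz[, 2]]]),
      guild = guildK[nz[, 1]], taxon = taxonK[nz[, 1]],
      count = as.integer(agg[nz]), stringsAsFactors = FALSE)
    counts <- counts[order(counts$sample, counts$guild, counts$taxon), ]
  } else {
    counts <- data.frame(sample = character(0), biome = character(0),
                         guild = character(0), taxon = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  tot <- colSums(m)
  unas <- colSums(m[!assigned, , drop = FALSE])
  samp <- data.frame(sample = samples,
                     biome = unname(biomes[samples]),
                     total = as.integer(tot),
                     unassigned = as.integer(unas),
                     stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  new("GuildedCounts", counts = counts, samples = samp)
}

#' Per-sample unassigned fraction (QC)
#'
#' Reference databases are biased towards cultured organisms, so a
#' substantial unassigned fraction is expected on real data; this reports
#' it per sample.
#'
#' @param gc A [GuildedCounts-class].
#' @return Named numeric vector, fraction of reads unassigned per sample.
#' @export
unassignedFraction <- function(gc) {
  with(gc@samples, stats::setNames(unassigned / pmax(total, 1), sample))
}

setMethod("show", "GuildedCounts", function(object) {
  cat("GuildedCounts:", nrow(object@samples), "sample(s),",
      length(unique(object@counts$guild)), "guild(s),",
      length(unique(object@counts$taxon)), "taxa\n")
  cat("  biomes:",
      paste(unique(object@samples$biome), collapse = ", "), "\n")
  uf <- unassignedFraction(object)
  cat(sprintf("  unassigned fraction: median %.3f (range %.3f-%.3f)\n",
              stats::median(uf), min(uf), max(uf)))
  invisible(NULL)
})

#' Read an OTU table (TSV or BIOM)
#'
#' TSV tables have OTU ids in the first column and one column per sample;
#' BIOM files are read through the `biomformat` package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`; guessed from the file extension by
#'   default.
#' @return Integer matrix, rows = OTUs, columns = samples.
#' @export
readOTUTable <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom"
              else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "integer"
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU table as TSV
#'
#' @param m OTU count matrix (rownames = OTU ids).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeOTUTable <- function(m, path) {
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column taxonomy TSV
#'
#' @param path TSV with columns `otu_id`, `lineage` (header optional but
#'   expected).
#' @return `data.frame` from [parseTaxonomy()].
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  parseTaxonomy(df)
}

#' Export a GuildedCounts partition as long-format TSV
#'
#' Columns: `sample`, `biome`, `guild`, `taxon`, `count`.
#'
#' @param gc A [GuildedCounts-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeGuildedCounts <- function(gc, path) {
  utils::write.table(gc@counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Accessors for GuildedCounts
#'
#' `guildCounts` returns the long-format count table; `sampleInfo` the
#' per-sample table (biome, total, unassigned).
#'
#' @param gc A [GuildedCounts-class].
#' @return A `data.frame`.
#' @export
guildCounts <- function(gc) gc@counts

#' @rdname guildCounts
#' @export
sampleInfo <- function(gc) gc@samples
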