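# Structural-homology classification of candidate consensus sequences
# from domain-coverage evidence, plus redundancy removal and HTT
# candidate flagging.
#
# Domain evidence is consumed as a table (consensus_id, domain, coverage,
# start, end) produced by external profile searches or by the simulator's
# truth tables; the package does not perform protein-domain discovery.

#' Default classification rule table
#'
#' Rules are applied in order; the first satisfied rule wins. The LINE
#' rule requires at least 80 percent coverage of both an endonuclease
#' (EN) and a reverse transcriptase (RT) domain on a consensus over
#' 800 bp. The LTR/ERV/DNA/PLE rules are documented package defaults and
#' fully user-configurable (the rule table is plain data).
#'
#' @return data.frame with columns class_label, required_domains
#'   (semicolon-separated domain:coverage pairs), min_length.
#' @export
default_class_rules <- function() {
  data.frame(
    class_label = c("LINE", "PLE", "ERV", "LTR", "DNA"),
    required_domains = c("EN:0.8;RT:0.8", "EN-GIY:0.8;RT:0.8",
                         "RT:0.8;RNase-H:0.8;gag:0.5",
                         "RT:0.8;RNase-H:0.8", "transposase:0.8"),
    min_length = c(800L, 800L, 800L, 800L, 800L),
    stringsAsFactors = FALSE)
}

#' Read / write a classification rule table as YAML
#' @param path YAML file.
#' @return data.frame of rules.
#' @export
read_class_rules <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y, function(r)
    data.frame(class_label = r$class_label,
               required_domains = r$required_domains,
               min_length = as.integer(r$min_length),
               stringsAsFactors = FALSE)))
}

#' @rdname read_class_rules
#' @param rules rule data.frame.
#' @export
write_class_rules <- function(rules, path) {
  yaml::write_yaml(lapply(seq_len(nrow(rules)), function(i)
    as.list(rules[i, ])), path)
  invisible(path)
}

parse_required <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(domain = vapply(kv, `[`, "", 1),
             min_coverage = as.numeric(vapply(kv, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Classify one consensus from its domain hits
#'
#' Order-independent in the domain-hit input (each domain's evidence is
#' reduced to its maximum coverage first). Consensi shorter than a rule's
#' minimum length are labelled `"excluded-short"`; consensi matching no
#' rule are `"unclassified"`.
#'
#' @param consensus_length length in bp (or a consensus object with `seq`).
#' @param domain_hits data.frame (consensus_id, domain, coverage, ...)
#'   restricted or not to this consensus; `consensus_id` is ignored if
#'   absent.
#' @param rules rule table (see [default_class_rules()]).
#' @return class label string.
#' @export
classify <- function(consensus_length, domain_hits,
                     rules = default_class_rules()) {
  stopifnot(nrow(rules) >= 1)
  if (is.list(consensus_length) && !is.null(consensus_length$seq))
    consensus_length <- nchar(consensus_length$seq)
  cov <- tapply(domain_hits$coverage, domain_hits$domain, max)
  for (i in seq_len(nrow(rules))) {
    req <- parse_required(rules$required_domains[i])
    have <- !is.na(cov[req$domain]) & cov[req$domain] >= req$min_coverage
    if (!all(have)) next
    if (consensus_length < rules$min_length[i]) return("excluded-short")
    return(rules$class_label[i])
  }
  "unclassified"
}

#' Remove redundant consensi from a library
#'
#' A consensus is dropped when it has >= `min_identity` percent pairwise
#' identity to, and >= `min_coverage` of its length covered by, a longer
#' consensus (coverage from merged hit intervals of an all-vs-all search
#' with the `default` preset). The longer member of a redundant pair
#' always survives; identical-length twins keep the lexicographically
#' earlier id. The operation is idempotent.
#'
#' @param library named character vector of consensus sequences.
#' @param min_identity percent identity threshold (default 94).
#' @param min_coverage fraction-of-length threshold (default 0.5).
#' @param params search parameters.
#' @return reduced named character vector; removed ids in attribute
#'   `removed`.
#' @export
remove_redundant <- function(library, min_identity = 94, min_coverage = 0.5,
                             params = search_params("default")) {
  n <- length(library)
  if (n <= 1) return(library)
  ids <- names(library)
  lens <- nchar(library)
  # order: longer first; ties by id so the later twin is dropped
  ord <- order(-lens, ids)
  drop <- logical(n)
  names(drop) <- ids
  for (a in seq_len(n - 1)) {
    ia <- ord[a]
    if (drop[ia]) next
    idx <- build_index(library[ia], params$word_size)
    for (b in (a + 1):n) {
      ib <- ord[b]
      if (drop[ib]) next
      h <- search_hits(library[ib], idx, params)
      h <- h[h$percent_identity >= min_identity, , drop = FALSE]
      if (nrow(h) == 0) next
      covered <- merged_interval_length(h$q_start, h$q_end)
      if (covered >= min_coverage * lens[ib]) drop[ib] <- TRUE
    }
  }
  out <- library[!drop]
  attr(out, "removed") <- ids[drop]
  if (any(drop))
    ht_log("remove_redundant: dropped ", sum(drop), " of ", n, ": ",
           paste(ids[drop], collapse = ", "))
  out
}

merged_interval_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0L; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) cur_e <- max(cur_e, end[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- start[i]; cur_e <- end[i] }
  }
  tot + (cur_e - cur_s)
}

#' Flag HTT candidate families by absence from close-relative genomes
#'
#' A family is a horizontal-transfer candidate only when its presence
#' call (see [call_presence()]) is `"absent"` in EVERY designated
#' close-relative genome; families found in all relatives are ancestrally
#' shared. A family found in some but not all relatives is treated as
#' shared (not a candidate) and logged as patchy.
#'
#' @param library named character vector of family consensi.
#' @param relative_genomes named list of genomes (each a named character
#'   vector of contigs) from the close relatives.
#' @param params search parameters (the close-relative screens use the
#'   `default` preset).
#' @return data.frame family / n_relatives_present / candidate / patchy.
#' @export
flag_htt_candidates <- function(library, relative_genomes,
                                params = search_params("default")) {
  stopifnot(length(relative_genomes) >= 1)
  idxs <- lapply(relative_genomes, build_index, word_size = params$word_size)
  rows <- lapply(names(library), function(fam) {
    calls <- vapply(idxs, function(ix)
      call_presence(screen_genome(library[fam], ix, params)), "")
    npres <- sum(calls != "absent")
    data.frame(family = fam, n_relatives_present = npres,
               candidate = npres == 0,
               patchy = npres > 0 && npres < length(idxs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$patchy))
    ht_log("flag_htt_candidates: patchy families (present in a strict ",
           "subset of relatives, excluded from candidacy): ",
           paste(out$family[out$patchy], collapse = ", "))
  out
}
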