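#' Text-based validation of the precision coding
#'
#' Recall utterances and movie-segment annotations are embedded as unit
#' vectors; cosine similarity between an utterance and the segments it
#' covers (matched) should exceed similarity to segments it does not cover
#' (mismatched), and matched similarity should be lower for Summary than
#' for Temporally Precise utterances. The built-in embedder is a
#' deterministic hashed bag-of-content-words model so the whole analysis
#' runs without any model download; a production sentence encoder can be
#' plugged in behind the same contract (a list with `name`, `dim` and an
#' `embed(texts)` function returning an n-by-dim matrix).
#'
#' @name text-similarity
NULL

# Deterministic string hash: polynomial rolling hash over UTF-8 code
# points, folded into [0, 2 * dim). Low half selects the index with sign
# +1, high half with sign -1.
hash_token <- function(token, dim) {
  h <- 0
  for (cp in utf8ToInt(token)) h <- (h * 31 + cp) %% (2 * dim)
  c(index = (h %% dim) + 1, sign = if (h < dim) 1 else -1)
}

#' Hashed bag-of-words embedding model
#'
#' Maps each text to an L2-normalized signed hashed bag of content words.
#' Identical texts map to identical vectors; texts with disjoint
#' vocabularies collide only by hash chance, so their cosine is near zero
#' with high probability at the default dimension.
#'
#' @param dim Embedding dimension (default 512).
#' @param stopwords,nonwords Tokens dropped before hashing.
#' @return An embedding model: list with `name`, `dim`, `embed`.
#' @export
toy_embedder <- function(dim = 512L, stopwords = default_stopwords(),
                         nonwords = default_nonwords()) {
  dim <- as.integer(dim)
  stopifnot(dim > 0)
  drop <- c(tolower(stopwords), tolower(nonwords))
  embed <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      s <- texts[i]
      if (is.na(s) || !nzchar(trimws(s))) next
      s <- gsub("[^a-z0-9' ]", " ", tolower(s))
      toks <- strsplit(trimws(s), "\\s+")[[1]]
      toks <- toks[nzchar(toks) & !toks %in% drop]
      for (tk in toks) {
        hs <- hash_token(tk, dim)
        out[i, hs["index"]] <- out[i, hs["index"]] + hs["sign"]
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
  list(name = paste0("toy-hash-", dim), dim = dim, embed = embed)
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine in `[-1, 1]`, or `NA` if either vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Row-normalize; zero rows stay zero so their cosine is reported 0 weight.
row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Utterance-to-covered-annotation similarity
#'
#' For every utterance with a segment span, the cosine between the
#' utterance embedding and each covered segment's annotation embedding,
#' averaged over covered segments (one composite score per utterance).
#' Utterances without a span (Other) get `NA`.
#'
#' @param transcript Transcript tibble.
#' @param seg Segmentation tibble.
#' @param model Embedding model (default [toy_embedder()]).
#' @return The transcript with a `similarity` column appended.
#' @export
utterance_similarity <- function(transcript, seg, model = toy_embedder()) {
  tr <- validate_transcript(transcript)
  seg_emb <- row_normalize(model$embed(seg$annotation))
  utt_emb <- row_normalize(model$embed(tr$text))
  cosines <- utt_emb %*% t(seg_emb)  # utterances x segments
  seg_ids <- seg$segment_id
  tr$similarity <- vapply(seq_len(nrow(tr)), function(i) {
    s <- tr$start_segment[i]
    e <- tr$end_segment[i]
    if (is.na(s) || is.na(e)) return(NA_real_)
    cols <- which(seg_ids >= s & seg_ids <= e)
    if (length(cols) == 0) {
      stop("utterance_similarity(): segment range ", s, "-", e,
           " not found in segmentation")
    }
    mean(cosines[i, cols])
  }, numeric(1))
  tr
}

#' Matched versus mismatched text similarity per subject and recall type
#'
#' For each subject and recall type (SUMMARY, PRECISE): `matched_mean` is
#' the mean composite similarity of that type's utterances to their covered
#' segments; `mismatched_mean` is the mean cosine between each utterance
#' and the segments outside its span (all of them by default, or a seeded
#' subsample of `cfg$mismatch_sample` per utterance); `difference` is
#' matched minus mismatched.
#'
#' @param transcript Labeled transcript tibble (one or more subjects).
#' @param seg Segmentation tibble.
#' @param model Embedding model.
#' @param cfg An [analysis_config()].
#' @param seed Optional seed for the mismatching subsample.
#' @param label_col Column holding the precision labels.
#' @return Tibble: `subject_id`, `label`, `n_utterances`, `matched_mean`,
#'   `mismatched_mean`, `difference`.
#' @export
matched_vs_mismatched <- function(transcript, seg, model = toy_embedder(),
                                  cfg = analysis_config(), seed = NULL,
                                  label_col = "label") {
  tr <- validate_transcript(transcript)
  tr$.label <- tr[[label_col]]
  seg_emb <- row_normalize(model$embed(seg$annotation))
  utt_emb <- row_normalize(model$embed(tr$text))
  cosines <- utt_emb %*% t(seg_emb)
  seg_ids <- seg$segment_id
  with_seed_if(seed, {
    per_utt <- purrr::map(seq_len(nrow(tr)), function(i) {
      s <- tr$start_segment[i]
      e <- tr$end_segment[i]
      if (is.na(s) || is.na(e)) {
        return(tibble::tibble(matched = NA_real_, mismatched = NA_real_))
      }
      in_cols <- which(seg_ids >= s & seg_ids <= e)
      out_cols <- setdiff(seq_along(seg_ids), in_cols)
      if (!is.null(cfg$mismatch_sample) &&
          length(out_cols) > cfg$mismatch_sample) {
        out_cols <- sample(out_cols, cfg$mismatch_sample)
      }
      tibble::tibble(
        matched = mean(cosines[i, in_cols]),
        mismatched = if (length(out_cols) > 0) {
          mean(cosines[i, out_cols])
        } else NA_real_
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_cols(tr[c("subject_id", ".label")], per_utt) |>
    dplyr::filter(.data$.label %in% c("SUMMARY", "PRECISE")) |>
    dplyr::group_by(subject_id = .data$subject_id, label = .data$.label) |>
    dplyr::summarise(
      n_utterances = dplyr::n(),
      matched_mean = mean(.data$matched, na.rm = TRUE),
      mismatched_mean = mean(.data$mismatched, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mismatched_mean = ifelse(is.nan(.data$mismatched_mean), NA_real_,
                               .data$mismatched_mean),
      difference = .data$matched_mean - .data$mismatched_mean
    )
}

#' Group-level text-similarity contrasts
#'
#' Paired two-tailed t-tests across subjects: matched vs mismatched
#' similarity within each recall type, and matched(PRECISE) vs
#' matched(SUMMARY). Degenerate zero-variance differences are flagged, not
#' errors.
#'
#' @param results Output of [matched_vs_mismatched()] over >= 2 subjects.
#' @return Tibble with one row per contrast plus [one_sample_t()] columns.
#' @export
group_text_contrast <- function(results) {
  wide <- results |>
    dplyr::select("subject_id", "label", "matched_mean", "mismatched_mean") |>
    tidyr::pivot_wider(names_from = "label",
                       values_from = c("matched_mean", "mismatched_mean"))
  if (nrow(wide) < 2) {
    stop("group_text_contrast() needs at least 2 subjects, got ", nrow(wide))
  }
  contrast <- function(name, x, y) {
    ok <- !is.na(x) & !is.na(y)
    dplyr::bind_cols(tibble::tibble(contrast = name),
                     paired_t(x[ok], y[ok]))
  }
  dplyr::bind_rows(
    contrast("matched_vs_mismatched_PRECISE",
             wide$matched_mean_PRECISE, wide$mismatched_mean_PRECISE),
    contrast("matched_vs_mismatched_SUMMARY",
             wide$matched_mean_SUMMARY, wide$mismatched_mean_SUMMARY),
    contrast("matched_PRECISE_vs_SUMMARY",
             wide$matched_mean_PRECISE, wide$matched_mean_SUMMARY)
  )
}
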