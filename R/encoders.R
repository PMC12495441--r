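# 31-bit polynomial rolling hash of a string (no external digest dependency).
# Used for cache keys and for seeding the synthetic provider; cache entries
# also store the exact input so collisions can never return a wrong value.
.string_hash <- function(s, seed = 0L) {
  h <- (seed %% 2147483647) + 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

#' Deterministic synthetic embedding provider
#'
#' A stand-in encoder used for testing and offline development: it emulates
#' the interface of a frozen pretrained encoder (per-token embedding rows of
#' a fixed width) without requiring model weights. The vector for a token is
#' a pure pseudo-random function of (token identity, position bucket, global
#' seed), so embeddings are deterministic, fast, distinct across seeds, and
#' distinct across inputs with overwhelming probability. Tokenization is per
#' character (SMILES) or per residue (proteins).
#'
#' @param dim Embedding width (e.g. 512 for ligands, 640 for proteins).
#' @param seed Global provider seed.
#' @param max_tokens Maximum input length accepted by the provider.
#' @param position_buckets Number of position buckets mixed into the token
#'   hash, giving mild position sensitivity.
#' @return A provider object (class `dta_provider`) usable with
#'   [embed_ligand()] / [embed_protein()].
#' @export
synthetic_provider <- function(dim, seed = 0L, max_tokens = 512L,
                               position_buckets = 8L) {
  stopifnot(dim > 0, max_tokens > 0)
  memo <- new.env(parent = emptyenv())
  token_vec <- function(token, bucket) {
    key <- paste0(token, "@", bucket)
    if (!is.null(memo[[key]])) return(memo[[key]])
    h <- .string_hash(key, seed = seed * 7919L)
    v <- withr::with_seed(as.integer(h %% 2147483646) + 1L, stats::rnorm(dim))
    memo[[key]] <- v
    v
  }
  structure(list(
    id = sprintf("synthetic-d%d-s%d", dim, seed),
    dim = dim,
    max_tokens = max_tokens,
    tokenize = function(x) strsplit(x, "")[[1]],
    embed = function(tokens) {
      buckets <- (seq_along(tokens) - 1L) %% position_buckets
      t(mapply(token_vec, tokens, buckets))
    }
  ), class = "dta_provider")
}

.embed_string <- function(provider, x, what) {
  stopifnot(inherits(provider, "dta_provider"))
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    rlang::abort(paste0("cannot embed an empty ", what))
  }
  tokens <- provider$tokenize(x)
  if (length(tokens) > provider$max_tokens) {
    rlang::abort(sprintf("%s of %d tokens exceeds the provider limit of %d",
                         what, length(tokens), provider$max_tokens))
  }
  values <- provider$embed(tokens)
  dimnames(values) <- NULL
  structure(list(values = values, tokens = length(tokens),
                 dim = provider$dim, provider_id = provider$id,
                 content_key = embedding_key(provider, x), input = x),
            class = "dta_embedding")
}

#' Embed a ligand SMILES string
#'
#' One embedding row per SMILES token under the provider's tokenizer
#' (characters for the synthetic provider). Strings longer than the
#' provider's token limit (512 for ligand encoders) are an error.
#'
#' @param provider A provider object such as [synthetic_provider()].
#' @param smiles One canonical SMILES string.
#' @param cache Optional [embedding_cache()]; on a hit the provider is not
#'   invoked.
#' @return A `dta_embedding`: list with `values` (tokens x dim matrix),
#'   `tokens`, `dim`, `provider_id`, `content_key`.
#' @export
embed_ligand <- function(provider, smiles, cache = NULL) {
  .embed_cached(provider, smiles, "SMILES string", cache)
}

#' Embed a protein sequence
#'
#' One embedding row per residue. Proteins are expected within the curation
#' length bounds; sequences beyond the provider limit (2500 residues by
#' convention for protein encoders) are an error.
#'
#' @inheritParams embed_ligand
#' @param sequence One amino-acid sequence.
#' @return A `dta_embedding` (residues x dim).
#' @export
embed_protein <- function(provider, sequence, cache = NULL) {
  .embed_cached(provider, sequence, "protein sequence", cache)
}

.embed_cached <- function(provider, x, what, cache) {
  if (is.null(cache)) return(.embed_string(provider, x, what))
  key <- embedding_key(provider, x)
  hit <- cache_get(cache, key, input = x)
  if (!is.null(hit)) return(hit)
  emb <- .embed_string(provider, x, what)
  cache_put(cache, emb)
  emb
}

#' Content key for an embedding
#'
#' Digest of (provider id, exact input string); the cache index key.
#'
#' @inheritParams embed_ligand
#' @param x Input string.
#' @return Character key.
#' @export
embedding_key <- function(provider, x) {
  sprintf("%s-%d-%d", provider$id, .string_hash(paste0(provider$id, "\r", x)),
          nchar(x))
}

#' In-memory embedding cache
#'
#' Frozen encoders always produce the same embedding for the same input, so
#' embeddings are computed once and reused across the K submodels of an
#' ensemble: with caching, training invokes each provider at most once per
#' unique input string. Entries carry the exact input and a checksum;
#' [cache_get()] verifies both, so a corrupted or colliding entry is reported
#' or treated as a miss, never returned wrong.
#'
#' @return A cache object (class `dta_cache`) with hit/miss counters.
#' @export
embedding_cache <- function() {
  structure(list(store = new.env(parent = emptyenv()),
                 stats = new.env(parent = emptyenv())),
            class = "dta_cache")
}

#' @rdname embedding_cache
#' @param cache A `dta_cache`.
#' @param key Content key from [embedding_key()].
#' @param input Optional exact input string for verification.
#' @return `cache_get()`: the stored `dta_embedding`, or `NULL` on a miss.
#' @export
cache_get <- function(cache, key, input = NULL) {
  entry <- cache$store[[key]]
  if (is.null(entry)) {
    cache$stats$misses <- (cache$stats$misses %||% 0L) + 1L
    return(NULL)
  }
  if (!is.null(input) && !identical(entry$input, input)) {
    cache$stats$misses <- (cache$stats$misses %||% 0L) + 1L
    return(NULL)  # key collision: treat as a miss, never return a wrong value
  }
  if (!isTRUE(all.equal(sum(entry$values), entry$checksum))) {
    rlang::abort("embedding cache entry failed its checksum")
  }
  cache$stats$hits <- (cache$stats$hits %||% 0L) + 1L
  structure(unclass(entry)[setdiff(names(entry), "checksum")],
            class = "dta_embedding")
}

#' @rdname embedding_cache
#' @param embedding A `dta_embedding` to store under its `content_key`.
#' @return `cache_put()`: the cache, invisibly.
#' @export
cache_put <- function(cache, embedding) {
  stopifnot(inherits(embedding, "dta_embedding"))
  entry <- unclass(embedding)
  entry$checksum <- sum(entry$values)
  entry <- structure(entry, class = "dta_embedding")
  cache$store[[embedding$content_key]] <- entry
  invisible(cache)
}

#' @rdname embedding_cache
#' @return `cache_stats()`: named vector of hits and misses.
#' @export
cache_stats <- function(cache) {
  c(hits = cache$stats$hits %||% 0L, misses = cache$stats$misses %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
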