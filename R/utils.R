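# Plain array-based union-find with path compression; used for event
# coalescing and template merging (both need deterministic transitive closure).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj) # keep lowest index as root
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, sort(unique(roots)))
}
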