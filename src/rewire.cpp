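#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swaps (Maslov-Sneppen null model).
//
// Repeatedly picks two distinct edges (a,b) and (c,d), randomly orients the
// second, and proposes replacing them with (a,d) and (c,b).  Proposals that
// would create a self-loop or a multi-edge are rejected.  Each accepted swap
// leaves every vertex degree unchanged.  Randomness comes from R's RNG so
// results are reproducible under set.seed().
//
// `edges` is an m x 2 one-based edge list; the function stops after
// `n_swaps` accepted swaps or `max_tries` proposals, whichever comes first,
// and reports the accepted count in the "accepted" attribute.
// [[Rcpp::export]]
IntegerMatrix rewire_edgelist_cpp(IntegerMatrix edges, int n_nodes,
                                  int n_swaps, int max_tries) {
  const int m = edges.nrow();
  std::vector<int> from(m), to(m);
  std::vector<unsigned char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    from[e] = a;
    to[e] = b;
    adj[(size_t)a * n_nodes + b] = 1;
    adj[(size_t)b * n_nodes + a] = 1;
  }

  int accepted = 0, tries = 0;
  while (accepted < n_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposal: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;            // self-loop
    if (a == c || b == d) continue;            // no-op / duplicate pair
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b])
      continue;                                // multi-edge
    adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
    adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
    adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
    adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
    to[e1] = d;
    from[e2] = c;
    to[e2] = b;
    ++accepted;
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e] + 1;
    out(e, 1) = to[e] + 1;
  }
  out.attr("accepted") = accepted;
  return out;
}
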