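#include <Rcpp.h>
using namespace Rcpp;

// Parsimony scoring kernels.  Trees arrive as 1-based edge matrices in any
// row order; tips are numbered 1..ntip.  The kernels compute their own
// postorder.  Character states are bitmask sets over a per-character
// alphabet 0..nstates-1; a missing or inapplicable cell is the full mask.

static const int PS_INF = 1 << 28;

// Postorder edge sequence (children rows before parent rows), plus root.
static void postorder_edges(const IntegerMatrix &edge, int ntot,
                            std::vector<int> &order, int &root,
                            bool &binary) {
  int nedge = edge.nrow();
  std::vector<int> head(ntot + 1, -1), nxt(nedge, -1), nkid(ntot + 1, 0);
  std::vector<char> is_child(ntot + 1, 0);
  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0);
    nxt[e] = head[p];
    head[p] = e;
    ++nkid[p];
    is_child[edge(e, 1)] = 1;
  }
  root = -1;
  for (int e = 0; e < nedge; ++e)
    if (!is_child[edge(e, 0)]) { root = edge(e, 0); break; }
  if (root < 0) stop("edge matrix has no root (cycle?)");
  binary = true;
  for (int v = 1; v <= ntot; ++v)
    if (nkid[v] != 0 && nkid[v] != 2) binary = false;

  order.clear();
  order.reserve(nedge);
  // iterative DFS emitting edges on exit
  std::vector<std::pair<int, int> > stack;  // (node, edge taking us there)
  stack.push_back(std::make_pair(root, -1));
  std::vector<int> iter(ntot + 1);
  for (int v = 0; v <= ntot; ++v) iter[v] = head[v];
  while (!stack.empty()) {
    int v = stack.back().first;
    if (iter[v] >= 0) {
      int e = iter[v];
      iter[v] = nxt[e];
      stack.push_back(std::make_pair(edge(e, 1), e));
    } else {
      if (stack.back().second >= 0) order.push_back(stack.back().second);
      stack.pop_back();
    }
  }
  if ((int)order.size() != nedge)
    stop("edge matrix is not a connected rooted tree");
}

// Fitch counting for one unordered character on a strictly binary tree.
// Exact for bitmask tip sets on binary trees.
static int fitch_one(const IntegerMatrix &edge, const std::vector<int> &ord,
                     int ntip, int ntot, const int *tipmask,
                     std::vector<int> &buf) {
  for (int i = 0; i < ntip; ++i) buf[i] = tipmask[i];
  for (int i = ntip; i < ntot; ++i) buf[i] = 0;
  int steps = 0;
  for (size_t k = 0; k < ord.size(); ++k) {
    int e = ord[k];
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    int cm = buf[c];
    if (cm == 0) continue;              // all-missing subtree
    if (buf[p] == 0) { buf[p] = cm; continue; }
    int inter = buf[p] & cm;
    if (inter) buf[p] = inter;
    else { buf[p] |= cm; ++steps; }
  }
  return steps;
}

// Sankoff dynamic programming for one character with cost |i-j| (ordered)
// or 0/1 (unordered); exact on arbitrary (polytomous) trees.
static int sankoff_one(const IntegerMatrix &edge, const std::vector<int> &ord,
                       int root, int ntip, int ntot, const int *tipmask,
                       int ns, bool ordered, std::vector<int> &cost) {
  for (int v = 0; v < ntot; ++v)
    for (int s = 0; s < ns; ++s)
      cost[(size_t)v * ns + s] = (v < ntip)
        ? ((tipmask[v] >> s) & 1 ? 0 : PS_INF)
        : 0;
  for (size_t k = 0; k < ord.size(); ++k) {
    int e = ord[k];
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int s = 0; s < ns; ++s) {
      int best = PS_INF;
      for (int t = 0; t < ns; ++t) {
        int ct = cost[(size_t)c * ns + t];
        if (ct >= PS_INF) continue;
        int tr = ordered ? (s > t ? s - t : t - s) : (s == t ? 0 : 1);
        if (ct + tr < best) best = ct + tr;
      }
      int &pc = cost[(size_t)p * ns + s];
      pc = (best >= PS_INF) ? PS_INF : std::min(pc + best, PS_INF);
    }
  }
  int best = PS_INF;
  for (int s = 0; s < ns; ++s)
    best = std::min(best, cost[(size_t)(root - 1) * ns + s]);
  return best >= PS_INF ? 0 : best;   // all-missing character scores 0
}

// [[Rcpp::export(name = ".c_score_chars")]]
IntegerVector c_score_chars(IntegerMatrix edge, int ntip,
                            IntegerMatrix masks, IntegerVector type,
                            IntegerVector nstates) {
  int ntot = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    ntot = std::max(ntot, std::max(edge(e, 0), edge(e, 1)));
  std::vector<int> ord;
  int root;
  bool binary;
  postorder_edges(edge, ntot, ord, root, binary);

  int nchar = masks.ncol();
  IntegerVector out(nchar);
  std::vector<int> buf(ntot), cost, tip(ntip);
  for (int j = 0; j < nchar; ++j) {
    for (int i = 0; i < ntip; ++i) tip[i] = masks(i, j);
    int ns = nstates[j];
    if (ns <= 1) { out[j] = 0; continue; }
    if (type[j] == 0 && binary) {
      out[j] = fitch_one(edge, ord, ntip, ntot, tip.data(), buf);
    } else {
      cost.resize((size_t)ntot * ns);
      out[j] = sankoff_one(edge, ord, root, ntip, ntot, tip.data(), ns,
                           type[j] == 1, cost);
    }
  }
  return out;
}

// Weighted total length in one call (the hot path of tree search).
// [[Rcpp::export(name = ".c_tree_length")]]
double c_tree_length(IntegerMatrix edge, int ntip, IntegerMatrix masks,
                     IntegerVector type, IntegerVector nstates,
                     NumericVector weights) {
  IntegerVector steps = c_score_chars(edge, ntip, masks, type, nstates);
  double L = 0;
  for (int j = 0; j < steps.size(); ++j) L += steps[j] * weights[j];
  return L;
}

// Sankoff conditional cost table for one character: ntot x ns matrix of
// subtree costs (for most-parsimonious-reconstruction enumeration in R).
// [[Rcpp::export(name = ".c_sankoff_table")]]
IntegerMatrix c_sankoff_table(IntegerMatrix edge, int ntip,
                              IntegerVector tipmask, int ns, bool ordered) {
  int ntot = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    ntot = std::max(ntot, std::max(edge(e, 0), edge(e, 1)));
  std::vector<int> ord;
  int root;
  bool binary;
  postorder_edges(edge, ntot, ord, root, binary);
  std::vector<int> cost((size_t)ntot * ns), tip(ntip);
  for (int i = 0; i < ntip; ++i) tip[i] = tipmask[i];
  sankoff_one(edge, ord, root, ntip, ntot, tip.data(), ns, ordered, cost);
  IntegerMatrix out(ntot, ns);
  for (int v = 0; v < ntot; ++v)
    for (int s = 0; s < ns; ++s)
      out(v, s) = std::min(cost[(size_t)v * ns + s], PS_INF);
  return out;
}
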