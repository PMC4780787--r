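#include <Rcpp.h>
using namespace Rcpp;

// Gene-tree simulation under the network multispecies coalescent.
// Lineages are traced from the leaves toward the root: within an edge of
// length L carrying j lineages, pairwise coalescences occur at rate
// choose(j,2) (coalescent units); at a hybrid node each remaining lineage
// independently follows the minor parent edge with probability gamma.
// Remaining lineages coalesce above the root with certainty.

struct Lin {
  std::string s;   // newick of the subtree (no closing length)
  double a;        // age offset at entry of the current edge
  double r;        // age of the subtree root node
  unsigned mask;   // taxa below (bit i-1 for leaf i), for quartet shortcuts
};

static void merge_pair(std::vector<Lin> &v, int i, int j, double t,
                       bool build, int &fi, int &fj) {
  if (fi < 0) {
    // any singleton-singleton merge fixes the displayed quartet; the first
    // merge of a gene always joins two singletons
    unsigned mi = v[i].mask, mj = v[j].mask;
    if ((mi & (mi - 1)) == 0 && (mj & (mj - 1)) == 0) {
      int a = 0, b = 0;
      while (!((mi >> a) & 1)) a++;
      while (!((mj >> b) & 1)) b++;
      fi = a + 1; fj = b + 1;
      if (fi > fj) std::swap(fi, fj);
    }
  }
  Lin nw;
  double a1 = v[i].a + t, a2 = v[j].a + t;
  double anew = a1 > a2 ? a1 : a2;
  if (build) {
    char buf[64];
    nw.s.reserve(v[i].s.size() + v[j].s.size() + 32);
    nw.s += "(";
    nw.s += v[i].s;
    snprintf(buf, sizeof(buf), ":%.8g,", anew - v[i].r);
    nw.s += buf;
    nw.s += v[j].s;
    snprintf(buf, sizeof(buf), ":%.8g)", anew - v[j].r);
    nw.s += buf;
  }
  nw.a = anew - t;
  nw.r = anew;
  nw.mask = v[i].mask | v[j].mask;
  if (i > j) std::swap(i, j);
  v.erase(v.begin() + j);
  v[i] = nw;
}

static void coalesce(std::vector<Lin> &v, double L, bool build,
                     int &fi, int &fj) {
  double t = 0.0;
  while (v.size() >= 2) {
    int j = v.size();
    double rate = j * (j - 1) / 2.0;
    double dt = exp_rand() / rate;
    if (R_FINITE(L) && t + dt > L) break;
    t += dt;
    // uniform pair
    int i1 = (int)(unif_rand() * j); if (i1 == j) i1--;
    int i2 = (int)(unif_rand() * (j - 1)); if (i2 == j - 1) i2--;
    if (i2 >= i1) i2++;
    merge_pair(v, i1, i2, t, build, fi, fj);
  }
  if (R_FINITE(L)) for (size_t k = 0; k < v.size(); k++) v[k].a += L;
}

// [[Rcpp::export(name = ".sim_gene_trees_cpp")]]
List sim_gene_trees_cpp(IntegerMatrix edge, NumericVector len,
                        LogicalVector major, NumericVector gamma,
                        int ntax, int nnode, IntegerVector node_order,
                        CharacterVector labels, int ngenes, bool build_newick) {
  int E = edge.nrow();
  std::vector<std::vector<int> > kids(nnode + 1), pars(nnode + 1);
  for (int e = 0; e < E; e++) {
    kids[edge(e, 0)].push_back(e);
    pars[edge(e, 1)].push_back(e);
  }
  std::vector<std::string> labs(ntax);
  for (int i = 0; i < ntax; i++) labs[i] = as<std::string>(labels[i]);
  CharacterVector nwk(build_newick ? ngenes : 0);
  IntegerVector pi(ngenes), pj(ngenes);
  RNGScope scope;
  for (int g = 0; g < ngenes; g++) {
    std::vector<std::vector<Lin> > atedge(E);
    int fi = -1, fj = -1;
    for (int oi = 0; oi < node_order.size(); oi++) {
      int v = node_order[oi];
      std::vector<Lin> cur;
      if (v <= ntax) {
        Lin L0; L0.s = build_newick ? labs[v - 1] : std::string();
        L0.a = 0; L0.r = 0; L0.mask = 1u << (v - 1);
        cur.push_back(L0);
      } else {
        for (size_t ke = 0; ke < kids[v].size(); ke++) {
          std::vector<Lin> &in = atedge[kids[v][ke]];
          for (size_t k = 0; k < in.size(); k++) cur.push_back(in[k]);
          in.clear();
        }
      }
      if (pars[v].empty()) {
        coalesce(cur, R_PosInf, build_newick, fi, fj);
        if (build_newick) nwk[g] = cur[0].s + ";";
      } else if (pars[v].size() == 1) {
        int e = pars[v][0];
        atedge[e] = cur;
        coalesce(atedge[e], len[e], build_newick, fi, fj);
      } else {
        // hybrid node: route each lineage independently
        int emin = -1, emaj = -1;
        for (size_t k = 0; k < pars[v].size(); k++) {
          if (major[pars[v][k]]) emaj = pars[v][k]; else emin = pars[v][k];
        }
        double gm = gamma[emin];
        for (size_t k = 0; k < cur.size(); k++) {
          if (unif_rand() < gm) atedge[emin].push_back(cur[k]);
          else atedge[emaj].push_back(cur[k]);
        }
        coalesce(atedge[emin], len[emin], build_newick, fi, fj);
        coalesce(atedge[emaj], len[emaj], build_newick, fi, fj);
      }
    }
    pi[g] = fi; pj[g] = fj;
  }
  return List::create(_["newick"] = nwk, _["pair_i"] = pi, _["pair_j"] = pj);
}
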