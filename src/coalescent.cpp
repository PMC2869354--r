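#include <Rcpp.h>
using namespace Rcpp;

// Two-population Kingman coalescent with background lineages, tracking
// reciprocal monophyly of the focal samples and of the whole populations.
//
// Time unit: Ne generations, pairwise coalescence rate 1 (haploid
// convention). Each population starts with B lineages; the first n1 (n2)
// lineages of population 1 (2) are the focal samples. Populations evolve
// independently on [0, tau), then merge.
//
// Monophyly bookkeeping: every merge produces a lineage with known counts
// of population-1 tips, population-2 tips, focal-A tips and focal-B tips.
// A tip set S is monophyletic iff the first lineage containing all of S
// contains no member of the contrasting set (that lineage is S's MRCA).
//
// Uses R's RNG so results are reproducible via set.seed(). The draw order
// (one exponential, then one uniform pair index per merge) and the
// shift-removal of merged lineages match the pure-R reference
// implementation r_two_pop_rm() exactly, so the two can be compared
// replicate by replicate under a common seed.

struct Lineage { int c1, c2, ca, cb; };

struct MonoState {
  int n1, n2, B;
  bool monoA, monoB, monoP1, monoP2;
  bool doneA, doneB, doneP1, doneP2;
  void init(int n1_, int n2_, int B_) {
    n1 = n1_; n2 = n2_; B = B_;
    monoA = doneA = (n1 <= 1);
    monoB = doneB = (n2 <= 1);
    monoP1 = doneP1 = (B <= 1);
    monoP2 = doneP2 = (B <= 1);
  }
  void observe(const Lineage &l) {
    if (!doneA && l.ca == n1) { monoA = (l.cb == 0); doneA = true; }
    if (!doneB && l.cb == n2) { monoB = (l.ca == 0); doneB = true; }
    if (!doneP1 && l.c1 == B) { monoP1 = (l.c2 == 0); doneP1 = true; }
    if (!doneP2 && l.c2 == B) { monoP2 = (l.c1 == 0); doneP2 = true; }
  }
};

// map a uniform pair index m in [0, k(k-1)/2) to (i, j), i < j
static inline void pair_from_index(int m, int k, int &i, int &j) {
  int off = 0;
  for (i = 0; i < k - 1; ++i) {
    int block = k - 1 - i;
    if (m < off + block) { j = i + 1 + (m - off); return; }
    off += block;
  }
  i = k - 2; j = k - 1; // unreachable for valid m
}

// coalesce until one lineage remains or time exceeds tmax
static void run_phase(std::vector<Lineage> &lin, double tmax, MonoState &st) {
  double t = 0.0;
  while (lin.size() > 1) {
    int k = (int)lin.size();
    double rate = k * (k - 1) / 2.0;
    t += exp_rand() / rate;
    if (t > tmax) break;
    int npairs = k * (k - 1) / 2;
    int m = (int)(unif_rand() * npairs);
    if (m >= npairs) m = npairs - 1;
    int i, j;
    pair_from_index(m, k, i, j);
    lin[i].c1 += lin[j].c1; lin[i].c2 += lin[j].c2;
    lin[i].ca += lin[j].ca; lin[i].cb += lin[j].cb;
    st.observe(lin[i]);
    lin.erase(lin.begin() + j);
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_two_pop_rm(int n1, int n2, int B, double tau, int reps) {
  if (B < n1 || B < n2) stop("background size must be >= each sample size");
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1");
  if (tau < 0) stop("tau must be >= 0");
  LogicalMatrix out(reps, 2);
  for (int r = 0; r < reps; ++r) {
    MonoState st;
    st.init(n1, n2, B);
    std::vector<Lineage> pop1(B), pop2(B);
    for (int i = 0; i < B; ++i) {
      pop1[i] = Lineage{1, 0, (i < n1) ? 1 : 0, 0};
      pop2[i] = Lineage{0, 1, 0, (i < n2) ? 1 : 0};
    }
    run_phase(pop1, tau, st);
    run_phase(pop2, tau, st);
    pop1.insert(pop1.end(), pop2.begin(), pop2.end());
    run_phase(pop1, R_PosInf, st);
    out(r, 0) = st.monoA && st.monoB;
    out(r, 1) = st.monoP1 && st.monoP2;
  }
  return out;
}
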