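#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Balanced k-d tree over an n x d point matrix, with deterministic
// neighbor ordering: ties in distance are broken by the lower row index.
// Nodes are stored in an implicit array (median split, recursive).

struct KdNode {
  int point;      // row index into the point matrix
  int axis;
  int left, right; // node indices, -1 if none
};

struct KdTree {
  NumericMatrix pts;
  std::vector<KdNode> nodes;
  int root;

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int axis = depth % pts.ncol();
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       if (pts(a, axis) != pts(b, axis))
                         return pts(a, axis) < pts(b, axis);
                       return a < b;
                     });
    KdNode nd;
    nd.point = idx[mid];
    nd.axis = axis;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    nodes[me].left = build(idx, lo, mid, depth + 1);
    nodes[me].right = build(idx, mid + 1, hi, depth + 1);
    return me;
  }
};

static double sqdist(const NumericMatrix& pts, int i, const NumericVector& q) {
  double s = 0.0;
  for (int j = 0; j < pts.ncol(); ++j) {
    double d = pts(i, j) - q[j];
    s += d * d;
  }
  return s;
}

// max-heap entry: (squared distance, point index); worst candidate on top.
// Ordering makes (larger dist) OR (equal dist, larger index) "worse", so the
// retained k-set is exactly the brute-force head of order(dist, index).
struct HeapEntry {
  double d2;
  int idx;
  bool operator<(const HeapEntry& o) const {
    if (d2 != o.d2) return d2 < o.d2;
    return idx < o.idx;
  }
};

static void search(const KdTree& tr, int node, const NumericVector& q, int k,
                   std::priority_queue<HeapEntry>& heap) {
  if (node < 0) return;
  const KdNode& nd = tr.nodes[node];
  HeapEntry e{sqdist(tr.pts, nd.point, q), nd.point};
  if ((int)heap.size() < k) {
    heap.push(e);
  } else {
    const HeapEntry& worst = heap.top();
    if (e.d2 < worst.d2 || (e.d2 == worst.d2 && e.idx < worst.idx)) {
      heap.pop();
      heap.push(e);
    }
  }
  double diff = q[nd.axis] - tr.pts(nd.point, nd.axis);
  int near = diff <= 0 ? nd.left : nd.right;
  int far = diff <= 0 ? nd.right : nd.left;
  search(tr, near, q, k, heap);
  // visit far side if the splitting plane could hold a candidate at least
  // as good as the current worst (<= keeps exact index tie-breaks)
  if ((int)heap.size() < k || diff * diff <= heap.top().d2)
    search(tr, far, q, k, heap);
}

// [[Rcpp::export(name = ".kdtree_build")]]
SEXP kdtree_build(NumericMatrix pts) {
  KdTree* tr = new KdTree();
  tr->pts = pts;
  std::vector<int> idx(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) idx[i] = i;
  tr->nodes.reserve(pts.nrow());
  tr->root = tr->build(idx, 0, pts.nrow(), 0);
  return XPtr<KdTree>(tr, true);
}

// An XPtr read back from a serialized object dangles; callers test this
// and rebuild the tree from the stored training matrix.
// [[Rcpp::export(name = ".kdtree_valid")]]
bool kdtree_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// Returns 1-based neighbor indices (n_query x k) ordered by increasing
// distance, ties by increasing training index, plus the distances.
// [[Rcpp::export(name = ".kdtree_query")]]
List kdtree_query(SEXP tree, NumericMatrix queries, int k) {
  XPtr<KdTree> tr(tree);
  int nq = queries.nrow();
  IntegerMatrix nn(nq, k);
  NumericMatrix nd(nq, k);
  for (int i = 0; i < nq; ++i) {
    NumericVector q = queries(i, _);
    std::priority_queue<HeapEntry> heap;
    search(*tr, tr->root, q, k, heap);
    for (int j = (int)heap.size() - 1; j >= 0; --j) {
      nn(i, j) = heap.top().idx + 1;
      nd(i, j) = std::sqrt(heap.top().d2);
      heap.pop();
    }
  }
  return List::create(_["index"] = nn, _["dist"] = nd);
}
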