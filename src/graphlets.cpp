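#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Orbit counting for graphlets on 2-4 nodes (orbits 0-14, standard numbering:
// 0 edge; 1/2 path-3 end/mid; 3 triangle; 4/5 path-4 end/mid; 6/7 claw
// leaf/centre; 8 cycle-4; 9/10/11 tailed-triangle tail/cycle/attachment;
// 12/13 diamond rim/hub; 14 complete-4).
//
// Size-3 graphlets are counted by neighbour-pair scanning; size-4 graphlets by
// ESU (Wernicke) enumeration of connected induced subgraphs, each visited
// exactly once, then classified by its internal degree sequence.

static inline bool adj(const std::vector<std::vector<int> > &nb, int a, int b) {
    const std::vector<int> &v = nb[a];
    return std::binary_search(v.begin(), v.end(), b);
}

static void classify4(const std::vector<std::vector<int> > &nb,
                      const int *s, IntegerMatrix &O) {
    int deg[4] = {0, 0, 0, 0};
    int e = 0;
    for (int i = 0; i < 4; i++)
        for (int j = i + 1; j < 4; j++)
            if (adj(nb, s[i], s[j])) { e++; deg[i]++; deg[j]++; }
    int maxdeg = std::max(std::max(deg[0], deg[1]), std::max(deg[2], deg[3]));
    for (int i = 0; i < 4; i++) {
        int orb;
        switch (e) {
        case 3:
            if (maxdeg == 3) orb = (deg[i] == 3) ? 7 : 6;   // claw
            else             orb = (deg[i] == 2) ? 5 : 4;   // path-4
            break;
        case 4:
            if (maxdeg == 3) {                               // tailed triangle
                if (deg[i] == 1) orb = 9;
                else if (deg[i] == 2) orb = 10;
                else orb = 11;
            } else orb = 8;                                  // cycle-4
            break;
        case 5:
            orb = (deg[i] == 2) ? 12 : 13;                   // diamond
            break;
        default:
            orb = 14;                                        // K4
        }
        O(s[i], orb)++;
    }
}

// [[Rcpp::export]]
IntegerMatrix orbit_counts_cpp(int n, IntegerMatrix edges) {
    std::vector<std::vector<int> > nb(n);
    int m = edges.nrow();
    for (int e = 0; e < m; e++) {
        int a = edges(e, 0), b = edges(e, 1);
        if (a == b) continue;
        nb[a].push_back(b);
        nb[b].push_back(a);
    }
    for (int i = 0; i < n; i++) {
        std::sort(nb[i].begin(), nb[i].end());
        nb[i].erase(std::unique(nb[i].begin(), nb[i].end()), nb[i].end());
    }

    IntegerMatrix O(n, 15);

    for (int i = 0; i < n; i++) O(i, 0) = (int) nb[i].size();

    // size 3: every (centre v, neighbour pair u<w) is scanned once; a triangle
    // is met once per member acting as centre, which is exactly its orbit-3
    // increment, and an induced path once with its true centre.
    for (int v = 0; v < n; v++) {
        const std::vector<int> &nv = nb[v];
        for (size_t i = 0; i + 1 < nv.size(); i++)
            for (size_t j = i + 1; j < nv.size(); j++) {
                int u = nv[i], w = nv[j];
                if (adj(nb, u, w)) {
                    O(v, 3)++;
                } else {
                    O(v, 2)++;
                    O(u, 1)++;
                    O(w, 1)++;
                }
            }
    }

    // size 4 via ESU: subgraphs rooted at their minimum vertex.
    std::vector<char> insub(n, 0);
    for (int v = 0; v < n; v++) {
        // depth 1
        std::vector<int> ext1;
        for (size_t i = 0; i < nb[v].size(); i++)
            if (nb[v][i] > v) ext1.push_back(nb[v][i]);
        insub[v] = 1;
        for (size_t a = 0; a < ext1.size(); a++) {
            int w1 = ext1[a];
            insub[w1] = 1;
            // extension: remaining ext1 beyond a, plus exclusive nbrs of w1
            std::vector<int> ext2(ext1.begin() + a + 1, ext1.end());
            for (size_t i = 0; i < nb[w1].size(); i++) {
                int u = nb[w1][i];
                if (u > v && !insub[u] && !adj(nb, u, v)) ext2.push_back(u);
            }
            for (size_t b = 0; b < ext2.size(); b++) {
                int w2 = ext2[b];
                insub[w2] = 1;
                std::vector<int> ext3(ext2.begin() + b + 1, ext2.end());
                // extend with exclusive neighbours of w2 w.r.t. {v, w1}
                for (size_t i = 0; i < nb[w2].size(); i++) {
                    int u = nb[w2][i];
                    if (u > v && !insub[u] && !adj(nb, u, v) && !adj(nb, u, w1))
                        ext3.push_back(u);
                }
                for (size_t c = 0; c < ext3.size(); c++) {
                    int w3 = ext3[c];
                    int s[4] = {v, w1, w2, w3};
                    classify4(nb, s, O);
                }
                insub[w2] = 0;
            }
            insub[w1] = 0;
        }
        insub[v] = 0;
    }
    return O;
}
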