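#include <Rcpp.h>
#include <cctype>
#include <cstdarg>
#include <string>

using namespace Rcpp;

// Double metaphone (Philips 2000): primary and alternate consonant-skeleton
// codes with the full rule set for ambiguous pronunciations (germanic /
// slavic / romance contexts). Operates on ASCII; input is uppercased and
// padded so lookahead never walks off the end.

namespace {

struct DM {
  std::string word;   // uppercased, padded with trailing spaces
  int length;         // length of the real word
  int last;           // index of last real character
  std::string primary, secondary;
  bool alternate;
  int maxlen;

  explicit DM(const std::string &in, int maxlen_) : alternate(false), maxlen(maxlen_) {
    word.reserve(in.size() + 5);
    for (size_t i = 0; i < in.size(); ++i)
      word.push_back((char)std::toupper((unsigned char)in[i]));
    length = (int)word.size();
    last = length - 1;
    word.append(5, ' ');
  }

  char at(int i) const {
    if (i < 0 || i >= (int)word.size()) return '\0';
    return word[i];
  }

  bool is_vowel(int i) const {
    const char c = at(i);
    return c == 'A' || c == 'E' || c == 'I' || c == 'O' || c == 'U' || c == 'Y';
  }

  // true if word[start, start+len) equals any of the candidate strings
  bool string_at(int start, int len, int n, ...) const {
    if (start < 0) return false;
    const std::string frag = word.substr(start, len);
    va_list ap;
    va_start(ap, n);
    bool hit = false;
    for (int k = 0; k < n; ++k) {
      const char *cand = va_arg(ap, const char *);
      if (!hit && frag == cand) hit = true;
    }
    va_end(ap);
    return hit;
  }

  bool slavo_germanic() const {
    const std::string w = word.substr(0, length);
    return w.find('W') != std::string::npos || w.find('K') != std::string::npos ||
           w.find("CZ") != std::string::npos || w.find("WITZ") != std::string::npos;
  }

  void add(const char *p, const char *s) {
    primary += p;
    secondary += s;
    if (std::string(p) != s) alternate = true;
  }
  void add(const char *both) { add(both, both); }

  bool done() const {
    return (int)primary.size() >= maxlen && (int)secondary.size() >= maxlen;
  }
};

}  // namespace

static void dmeta_one(const std::string &input, int maxlen,
                      std::string &out_primary, std::string &out_secondary,
                      bool &out_alternate) {
  DM d(input, maxlen);
  int current = 0;

  // silent first letters and initial X
  if (d.string_at(0, 2, 5, "GN", "KN", "PN", "WR", "PS")) current = 1;
  if (d.at(0) == 'X') {
    d.add("S");
    current = 1;
  }

  while (!d.done() && current < d.length) {
    switch (d.at(current)) {
    case 'A': case 'E': case 'I': case 'O': case 'U': case 'Y':
      if (current == 0) d.add("A");
      ++current;
      break;

    case 'B':
      d.add("P");
      current += (d.at(current + 1) == 'B') ? 2 : 1;
      break;

    case '\xC7':  // C-cedilla
      d.add("S");
      ++current;
      break;

    case 'C':
      // germanic -ACH-
      if (current > 1 && !d.is_vowel(current - 2) &&
          d.string_at(current - 1, 3, 1, "ACH") &&
          (d.at(current + 2) != 'I' &&
           (d.at(current + 2) != 'E' ||
            d.string_at(current - 2, 6, 2, "BACHER", "MACHER")))) {
        d.add("K");
        current += 2;
        break;
      }
      if (current == 0 && d.string_at(current, 6, 1, "CAESAR")) {
        d.add("S");
        current += 2;
        break;
      }
      if (d.string_at(current, 4, 1, "CHIA")) {  // italian chianti
        d.add("K");
        current += 2;
        break;
      }
      if (d.string_at(current, 2, 1, "CH")) {
        if (current > 0 && d.string_at(current, 4, 1, "CHAE")) {  // michael
          d.add("K", "X");
          current += 2;
          break;
        }
        // greek roots at start
        if (current == 0 &&
            (d.string_at(current + 1, 5, 2, "HARAC", "HARIS") ||
             d.string_at(current + 1, 3, 4, "HOR", "HYM", "HIA", "HEM")) &&
            !d.string_at(0, 5, 1, "CHORE")) {
          d.add("K");
          current += 2;
          break;
        }
        // germanic, greek, or otherwise 'ch' as 'k'
        if (d.string_at(0, 4, 2, "VAN ", "VON ") || d.string_at(0, 3, 1, "SCH") ||
            d.string_at(current - 2, 6, 3, "ORCHES", "ARCHIT", "ORCHID") ||
            d.string_at(current + 2, 1, 2, "T", "S") ||
            ((d.string_at(current - 1, 1, 4, "A", "O", "U", "E") || current == 0) &&
             d.string_at(current + 2, 1, 10, "L", "R", "N", "M", "B", "H", "F", "V", "W", " "))) {
          d.add("K");
        } else {
          if (current > 0) {
            if (d.string_at(0, 2, 1, "MC")) d.add("K");
            else d.add("X", "K");
          } else {
            d.add("X");
          }
        }
        current += 2;
        break;
      }
      if (d.string_at(current, 2, 1, "CZ") &&
          !d.string_at(current - 2, 4, 1, "WICZ")) {
        d.add("S", "X");
        current += 2;
        break;
      }
      if (d.string_at(current + 1, 3, 1, "CIA")) {  // focaccia
        d.add("X");
        current += 3;
        break;
      }
      if (d.string_at(current, 2, 1, "CC") &&
          !(current == 1 && d.at(0) == 'M')) {
        if (d.string_at(current + 2, 1, 3, "I", "E", "H") &&
            !d.string_at(current + 2, 2, 1, "HU")) {
          if ((current == 1 && d.at(current - 1) == 'A') ||
              d.string_at(current - 1, 5, 2, "UCCEE", "UCCES")) {
            d.add("KS");
          } else {
            d.add("X");
          }
          current += 3;
          break;
        } else {
          d.add("K");
          current += 2;
          break;
        }
      }
      if (d.string_at(current, 2, 3, "CK", "CG", "CQ")) {
        d.add("K");
        current += 2;
        break;
      }
      if (d.string_at(current, 2, 3, "CI", "CE", "CY")) {
        if (d.string_at(current, 3, 3, "CIO", "CIE", "CIA")) d.add("S", "X");
        else d.add("S");
        current += 2;
        break;
      }
      d.add("K");
      if (d.string_at(current + 1, 2, 3, " C", " Q", " G")) current += 3;
      else if (d.string_at(current + 1, 1, 3, "C", "K", "Q") &&
               !d.string_at(current + 1, 2, 2, "CE", "CI"))
        current += 2;
      else
        ++current;
      break;

    case 'D':
      if (d.string_at(current, 2, 1, "DG")) {
        if (d.string_at(current + 2, 1, 3, "I", "E", "Y")) {  // edge
          d.add("J");
          current += 3;
        } else {  // edgar
          d.add("TK");
          current += 2;
        }
        break;
      }
      if (d.string_at(current, 2, 2, "DT", "DD")) {
        d.add("T");
        current += 2;
        break;
      }
      d.add("T");
      ++current;
      break;

    case 'F':
      d.add("F");
      current += (d.at(current + 1) == 'F') ? 2 : 1;
      break;

    case 'G':
      if (d.at(current + 1) == 'H') {
        if (current > 0 && !d.is_vowel(current - 1)) {
          d.add("K");
          current += 2;
          break;
        }
        if (current < 3) {
          if (current == 0) {
            if (d.at(current + 2) == 'I') d.add("J");  // ghislane
            else d.add("K");
            current += 2;
            break;
          }
        }
        // silent gh
        if ((current > 1 && d.string_at(current - 2, 1, 3, "B", "H", "D")) ||
            (current > 2 && d.string_at(current - 3, 1, 3, "B", "H", "D")) ||
            (current > 3 && d.string_at(current - 4, 1, 2, "B", "H"))) {
          current += 2;
          break;
        }
        if (current > 2 && d.at(current - 1) == 'U' &&
            d.string_at(current - 3, 1, 5, "C", "G", "L", "R", "T")) {  // laugh
          d.add("F");
        } else if (current > 0 && d.at(current - 1) != 'I') {
          d.add("K");
        }
        current += 2;
        break;
      }
      if (d.at(current + 1) == 'N') {
        if (current == 1 && d.is_vowel(0) && !d.slavo_germanic()) {
          d.add("KN", "N");
        } else if (!d.string_at(current + 2, 2, 1, "EY") &&
                   d.at(current + 1) != 'Y' && !d.slavo_germanic()) {
          d.add("N", "KN");
        } else {
          d.add("KN");
        }
        current += 2;
        break;
      }
      if (d.string_at(current + 1, 2, 1, "LI") && !d.slavo_germanic()) {
        d.add("KL", "L");  // tagliaro
        current += 2;
        break;
      }
      if (current == 0 &&
          (d.at(current + 1) == 'Y' ||
           d.string_at(current + 1, 2, 11, "ES", "EP", "EB", "EL", "EY", "IB",
                       "IL", "IN", "IE", "EI", "ER"))) {
        d.add("K", "J");
        current += 2;
        break;
      }
      if ((d.string_at(current + 1, 2, 1, "ER") || d.at(current + 1) == 'Y') &&
          !d.string_at(0, 6, 3, "DANGER", "RANGER", "MANGER") &&
          !d.string_at(current - 1, 1, 2, "E", "I") &&
          !d.string_at(current - 1, 3, 2, "RGY", "OGY")) {
        d.add("K", "J");
        current += 2;
        break;
      }
      if (d.string_at(current + 1, 1, 3, "E", "I", "Y") ||
          d.string_at(current - 1, 4, 2, "AGGI", "OGGI")) {
        if (d.string_at(0, 4, 2, "VAN ", "VON ") || d.string_at(0, 3, 1, "SCH") ||
            d.string_at(current + 1, 2, 1, "ET")) {
          d.add("K");
        } else if (d.string_at(current + 1, 4, 1, "IER ")) {
          d.add("J");
        } else {
          d.add("J", "K");
        }
        current += 2;
        break;
      }
      d.add("K");
      current += (d.at(current + 1) == 'G') ? 2 : 1;
      break;

    case 'H':
      // keep only when between vowels or at start before a vowel
      if ((current == 0 || d.is_vowel(current - 1)) && d.is_vowel(current + 1)) {
        d.add("H");
        current += 2;
      } else {
        ++current;
      }
      break;

    case 'J':
      if (d.string_at(current, 4, 1, "JOSE") || d.string_at(0, 4, 1, "SAN ")) {
        if ((current == 0 && d.at(current + 4) == ' ') ||
            d.string_at(0, 4, 1, "SAN ")) {
          d.add("H");
        } else {
          d.add("J", "H");
        }
        ++current;
        break;
      }
      if (current == 0 && !d.string_at(current, 4, 1, "JOSE")) {
        d.add("J", "A");
      } else if (d.is_vowel(current - 1) && !d.slavo_germanic() &&
                 (d.at(current + 1) == 'A' || d.at(current + 1) == 'O')) {
        d.add("J", "H");
      } else if (current == d.last) {
        d.add("J", " ");
      } else if (!d.string_at(current + 1, 1, 8, "L", "T", "K", "S", "N", "M",
                              "B", "Z") &&
                 !d.string_at(current - 1, 1, 3, "S", "K", "L")) {
        d.add("J");
      }
      current += (d.at(current + 1) == 'J') ? 2 : 1;
      break;

    case 'K':
      d.add("K");
      current += (d.at(current + 1) == 'K') ? 2 : 1;
      break;

    case 'L':
      if (d.at(current + 1) == 'L') {
        // spanish -illo / -alle endings
        if ((current == d.length - 3 &&
             d.string_at(current - 1, 4, 3, "ILLO", "ILLA", "ALLE")) ||
            ((d.string_at(d.last - 1, 2, 2, "AS", "OS") ||
              d.string_at(d.last, 1, 2, "A", "O")) &&
             d.string_at(current - 1, 4, 1, "ALLE"))) {
          d.add("L", " ");
          current += 2;
          break;
        }
        d.add("L");
        current += 2;
        break;
      }
      d.add("L");
      ++current;
      break;

    case 'M':
      d.add("M");
      if ((d.string_at(current - 1, 3, 1, "UMB") &&
           (current + 1 == d.last || d.string_at(current + 2, 2, 1, "ER"))) ||
          d.at(current + 1) == 'M')
        current += 2;
      else
        ++current;
      break;

    case 'N':
      d.add("N");
      current += (d.at(current + 1) == 'N') ? 2 : 1;
      break;

    case '\xD1':  // N-tilde
      d.add("N");
      ++current;
      break;

    case 'P':
      if (d.at(current + 1) == 'H') {
        d.add("F");
        current += 2;
        break;
      }
      d.add("P");
      current += d.string_at(current + 1, 1, 2, "P", "B") ? 2 : 1;
      break;

    case 'Q':
      d.add("K");
      current += (d.at(current + 1) == 'Q') ? 2 : 1;
      break;

    case 'R':
      // french -ier endings
      if (current == d.last && !d.slavo_germanic() &&
          d.string_at(current - 2, 2, 1, "IE") &&
          !d.string_at(current - 4, 2, 2, "ME", "MA")) {
        d.add("", "R");
      } else {
        d.add("R");
      }
      current += (d.at(current + 1) == 'R') ? 2 : 1;
      break;

    case 'S':
      if (d.string_at(current - 1, 3, 2, "ISL", "YSL")) {  // island
        ++current;
        break;
      }
      if (current == 0 && d.string_at(current, 5, 1, "SUGAR")) {
        d.add("X", "S");
        ++current;
        break;
      }
      if (d.string_at(current, 2, 1, "SH")) {
        if (d.string_at(current + 1, 4, 4, "HEIM", "HOEK", "HOLM", "HOLZ"))
          d.add("S");  // germanic
        else
          d.add("X");
        current += 2;
        break;
      }
      if (d.string_at(current, 3, 2, "SIO", "SIA") ||
          d.string_at(current, 4, 1, "SIAN")) {
        if (!d.slavo_germanic()) d.add("S", "X");
        else d.add("S");
        current += 3;
        break;
      }
      if ((current == 0 &&
           d.string_at(current + 1, 1, 4, "M", "N", "L", "W")) ||
          d.string_at(current + 1, 1, 1, "Z")) {
        d.add("S", "X");
        current += d.string_at(current + 1, 1, 1, "Z") ? 2 : 1;
        break;
      }
      if (d.string_at(current, 2, 1, "SC")) {
        if (d.at(current + 2) == 'H') {
          if (d.string_at(current + 3, 2, 6, "OO", "ER", "EN", "UY", "ED", "EM")) {
            if (d.string_at(current + 3, 2, 2, "ER", "EN")) d.add("X", "SK");
            else d.add("SK");
            current += 3;
            break;
          } else {
            if (current == 0 && !d.is_vowel(3) && d.at(3) != 'W') d.add("X", "S");
            else d.add("X");
            current += 3;
            break;
          }
        }
        if (d.string_at(current + 2, 1, 3, "I", "E", "Y")) {
          d.add("S");
          current += 3;
          break;
        }
        d.add("SK");
        current += 3;
        break;
      }
      if (current == d.last && d.string_at(current - 2, 2, 2, "AI", "OI")) {
        d.add("", "S");  // french resnais / artois
      } else {
        d.add("S");
      }
      current += d.string_at(current + 1, 1, 2, "S", "Z") ? 2 : 1;
      break;

    case 'T':
      if (d.string_at(current, 4, 1, "TION")) {
        d.add("X");
        current += 3;
        break;
      }
      if (d.string_at(current, 3, 2, "TIA", "TCH")) {
        d.add("X");
        current += 3;
        break;
      }
      if (d.string_at(current, 2, 1, "TH") || d.string_at(current, 3, 1, "TTH")) {
        if (d.string_at(current + 2, 2, 2, "OM", "AM") ||
            d.string_at(0, 4, 2, "VAN ", "VON ") || d.string_at(0, 3, 1, "SCH")) {
          d.add("T");  // thomas, thames, germanic
        } else {
          d.add("0", "T");
        }
        current += 2;
        break;
      }
      d.add("T");
      current += d.string_at(current + 1, 1, 2, "T", "D") ? 2 : 1;
      break;

    case 'V':
      d.add("F");
      current += (d.at(current + 1) == 'V') ? 2 : 1;
      break;

    case 'W':
      if (d.string_at(current, 2, 1, "WR")) {
        d.add("R");
        current += 2;
        break;
      }
      if (current == 0 && (d.is_vowel(current + 1) ||
                           d.string_at(current, 2, 1, "WH"))) {
        if (d.is_vowel(current + 1)) d.add("A", "F");  // wasserman
        else d.add("A");                               // wharton
        ++current;
        break;
      }
      if ((current == d.last && d.is_vowel(current - 1)) ||
          d.string_at(current - 1, 5, 4, "EWSKI", "EWSKY", "OWSKI", "OWSKY") ||
          d.string_at(0, 3, 1, "SCH")) {
        d.add("", "F");
        ++current;
        break;
      }
      if (d.string_at(current, 4, 2, "WICZ", "WITZ")) {
        d.add("TS", "FX");
        current += 4;
        break;
      }
      ++current;
      break;

    case 'X':
      if (!(current == d.last &&
            (d.string_at(current - 3, 3, 2, "IAU", "EAU") ||
             d.string_at(current - 2, 2, 2, "AU", "OU")))) {
        d.add("KS");
      }
      current += d.string_at(current + 1, 1, 2, "C", "X") ? 2 : 1;
      break;

    case 'Z':
      if (d.at(current + 1) == 'H') {
        d.add("J");  // chinese pinyin zh
        current += 2;
        break;
      }
      if (d.string_at(current + 1, 2, 3, "ZO", "ZI", "ZA") ||
          (d.slavo_germanic() && current > 0 && d.at(current - 1) != 'T')) {
        d.add("S", "TS");
      } else {
        d.add("S");
      }
      current += (d.at(current + 1) == 'Z') ? 2 : 1;
      break;

    default:
      ++current;
      break;
    }
  }

  if ((int)d.primary.size() > maxlen) d.primary.resize(maxlen);
  if ((int)d.secondary.size() > maxlen) d.secondary.resize(maxlen);
  // strip trailing spaces contributed by boundary rules
  while (!d.primary.empty() && d.primary[d.primary.size() - 1] == ' ')
    d.primary.resize(d.primary.size() - 1);
  while (!d.secondary.empty() && d.secondary[d.secondary.size() - 1] == ' ')
    d.secondary.resize(d.secondary.size() - 1);
  out_primary = d.primary;
  out_secondary = d.secondary;
  out_alternate = d.alternate;
}

// [[Rcpp::export(name = ".dmetaphone_cpp")]]
List dmetaphone_cpp(CharacterVector names, int maxlen) {
  const int n = names.size();
  CharacterVector prim(n), sec(n);
  LogicalVector alt(n);
  for (int k = 0; k < n; ++k) {
    std::string p, s;
    bool a;
    dmeta_one(as<std::string>(names[k]), maxlen, p, s, a);
    prim[k] = p;
    sec[k] = s;
    alt[k] = a;
  }
  return List::create(_["primary"] = prim, _["secondary"] = sec,
                      _["alternate"] = alt);
}
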