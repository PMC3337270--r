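# Default negation trigger phrases, after the published NegEx rule set.
# Sections: [PRE] pre-negation, [POST] post-negation, [PSEUDO] pseudo-negation
# (phrases containing a trigger word that do not negate), [TERM] scope
# terminators. One phrase per line; '#' starts a comment.
[PRE]
no
not
without
denies
denied
deny
never had
no evidence of
no sign of
no signs of
no history of
absence of
negative for
free of
rules out
ruled out
rule out
cannot see
checked for
declined
fails to reveal
[POST]
unlikely
was ruled out
is ruled out
are ruled out
be ruled out
was negative
were negative
free
[PSEUDO]
no increase
no change
no definite change
not extend
not cause
not certain if
not certain whether
gram negative
without difficulty
not necessarily
not rule out
not ruled out
not been ruled out
[TERM]
but
however
although
though
except
apart from
aside from
yet
which
still
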