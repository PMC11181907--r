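patients
may
treatment
the
of
and
in
to
with
for
be
is
or
that
should
have
use
not
been
are
as
this
dose
therapy
clinical
reported
during
has
was
were
can
if
at
on
an
by
from
other
than
these
when
risk
who
all
also
including
following
more
no
which
such
used
after
severe
cases
occur
observed
studies
administration
dosage
daily
recommended
monitor
monitoring
discontinue
discontinued
initiation
initiated
receiving
concomitant
prior
before
their
because
most
some
any
less
common
rare
occurred
events
event
reactions
reaction
adverse
serious
symptoms
signs
including
associated
increased
decreased
reduced
greater
higher
lower
within
between
without
both
each
one
two
three
days
weeks
months
years
time
times
first
second
study
trial
trials
group
groups
placebo
versus
compared
rate
rates
incidence
frequency
approximately
about
however
although
while
well
known
new
possible
potential
required
require
necessary
appropriate
caution
care
careful
consider
considered
advise
advised
inform
informed
women
men
elderly
pediatric
adults
adult
children
age
older
younger
history
condition
conditions
disease
diseases
disorder
disorders
generally
usually
often
sometimes
rarely
frequently
immediately
promptly
closely
every
per
once
twice
under
over
above
below
until
since
through
against
among
across
where
there
here
same
different
certain
several
many
few
number
based
due
result
results
effect
effects
information
section
see
refer
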