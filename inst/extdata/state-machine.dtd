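<!-- Formal schema of the state-machine model dialect: one machine per
     document; transitions follow Event-Condition-Action semantics. -->
<!ELEMENT stateMachine (state+)>
<!ATTLIST stateMachine
  id      CDATA #REQUIRED
  initial CDATA #REQUIRED>
<!ELEMENT state (transition*)>
<!ATTLIST state
  name    CDATA #REQUIRED
  final   (true|false) "false"
  onError CDATA #IMPLIED>
<!ELEMENT transition (action?)>
<!ATTLIST transition
  event CDATA "step"
  guard CDATA "true"
  to    CDATA #REQUIRED>
<!ELEMENT action (bind*)>
<!ATTLIST action
  op        CDATA #REQUIRED
  resultKey CDATA #IMPLIED>
<!ELEMENT bind EMPTY>
<!ATTLIST bind
  param CDATA #REQUIRED
  from  (context|literal) #REQUIRED
  key   CDATA #IMPLIED
  value CDATA #IMPLIED>
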