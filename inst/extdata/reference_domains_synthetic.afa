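>ref01 synthetic reference domain
ERRNRAKVKRRRSKKKEAFRELGFLIPTGVPDLASIWHFWEYIQEVDWKNRHLEL
>ref02 synthetic reference domain
KRRTIMKEKRRPFKISTAFEELEMLILDGKFDRESQGAMQHFIWEFQLKQELIEV
>ref03 synthetic reference domain
KRRNRAKNKRRRTKQNEGFEILRFILNADKKDKMSYHAAFEYIVELQRKNEDLEA
>ref04 synthetic reference domain
KRRNRIKLKRVESKWNYAFESLWTLIPAGGPDTEAILAAIEMIDELQRKHERSFC
>ref05 synthetic reference domain
KRRHRIKEKPRRSKILEANVILRCLIPRGKSDKPSRLAEIEYIRMLHRHRQRAKA
>ref06 synthetic reference domain
KRRPRIKEKRRRYKGNLAFPEYRSLIPFGPPDKASMNAASEWICETALKNEAWEA
>ref07 synthetic reference domain
KRKNRDKEKRRWRKDNTAFPILTSLIPEGKQDKHSITASLEAIQELWRKNMRLEQ
>ref08 synthetic reference domain
KRRWRIKFKRRMSKIGEAFEELRSLILAGQDDPRSIMAAIEYINERQPKLQAPTQ
>ref09 synthetic reference domain
KRRGRVKEPRRCEKIWNAFYALLHLIFYGAWCYASILAPIENIQEVQPKIHRLIS
>ref10 synthetic reference domain
KRRIRCAAKRRRSKITLAFPRLRSLIYFGKPDDASLLAWEEFIDEYGTKTESVPA
>ref11 synthetic reference domain
KERNRHKSKRRPTKLHEAFEELSSLIAAGYPDKGSQWADIEYIQEQNIKSIRFIA
>ref12 synthetic reference domain
KRRSRIKFKRRTLLWNGAFPPLTNLIMAGLDDAASQLAADEPWQELHRKNIMLYY
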