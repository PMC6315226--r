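abuya
achieng
adede
adera
adhiambo
agutu
ahenda
ajwang
akeyo
akinyi
akoth
aluoch
amolo
andiego
anyango
apondi
arunga
asewe
atieno
auma
awino
awuor
ayieko
ayoo
barasa
bett
bosire
chacha
chebet
cheruiyot
chweya
gati
gaya
gekonge
gor
jagero
juma
kajwang
kamau
kariuki
kaunda
keter
kibet
kilonzo
kimani
kimutai
kinoti
kiprono
kiptoo
kirui
kisia
kogello
koech
korir
kosgei
kuria
langat
lumumba
machoka
madowo
magak
maina
makori
masinde
matiangi
mbeche
mboya
migwambo
miruka
misik
mogaka
momanyi
mong'are
moraa
mosoti
muga
mugo
muhoro
mukabana
muriithi
musyoka
mutua
mwangi
mwaura
ndege
ndeda
ndiege
ndong'a
ngala
ngesa
njagi
njoroge
njue
nyabola
nyaboke
nyagaka
nyakundi
nyamweya
nyangau
nyariki
nyasani
obado
obara
obong'o
obonyo
obura
ochanda
ochieng
ochola
ochuka
odede
odek
odero
odhiambo
odinga
odiwuor
odongo
oduol
oduor
oduya
oganga
ogega
ogembo
ogendo
ogola
ogolla
ogonda
ogutu
ojal
ojode
ojwang
okach
okal
okech
okelo
okemwa
okeyo
okinda
okombo
okong'o
okoth
okumu
olago
olale
olang'
oloo
oluoch
omamo
ombachi
ombara
ombija
ombogo
omedo
omieno
omolo
omondi
omune
onchiri
ondiek
onditi
oneya
ongadi
ongeri
ong'ondo
oniang'o
onsongo
onyando
onyango
onyinkwa
ooko
oombe
opanga
opiyo
oraro
orengo
orinda
orwa
osano
oseko
osewe
osogo
otieno
otiende
otiato
ouko
ouma
owino
owiti
owuor
oyier
oyoo
oyugi
ragwar
rapando
ratego
riaga
rono
rotich
ruto
sang
sewe
simiyu
tanui
too
towett
wabwile
wafula
waiganjo
wairimu
wakiaga
wamalwa
wambua
wandera
wanga
wanjala
wanyama
wanyonyi
wasonga
waudo
wekesa
were
yego
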